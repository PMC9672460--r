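# saapk

Whole-body PBPK simulation and clinical pharmacokinetic analysis of
**salvianolic acid A (SAA)** — a water-soluble phenolic acid from *Salvia
miltiorrhiza* under development for coronary heart disease, dosed
intravenously as a sodium salt.

The package is aimed at clinical pharmacologists and modelling-and-
simulation scientists working with first-in-human ascending-dose IV data.
It provides, as one tested pipeline:

* a **transporter-saturable whole-body PBPK simulator**: 14
  permeability-limited tissue compartments (vascular + extravascular
  sub-compartments, exchange by a permeability–surface product acting on
  unbound drug) linked by venous/arterial blood with lung in series;
  saturable hepatic uptake (OATP1B1) and biliary efflux (P-gp) as
  Michaelis–Menten fluxes; zero-order infusion input with exact on/off
  event handling; a stiff 4(3) Rosenbrock integrator in C++ with analytic
  Jacobian;
* **tissue:plasma partition coefficients** by the Rodgers–Leahy–Rowland
  tissue-composition method (monoprotic-acid form) or from measured
  tissue-distribution ratios;
* **non-compartmental analysis**: Cmax, AUC0–t/AUC0–inf/AUCτ
  (linear-up/log-down), λz with adjusted-R² terminal-window selection,
  t1/2, CL, Vd, Cavg, fluctuation `(Cmax−Cmin)/Cavg×100`, accumulation
  index `1/(1−exp(−λz·τ))`;
* **dose proportionality** by the power model `ln(Y) = α + β·ln(dose)`
  with the bioequivalence-scaled acceptance range
  `(1 + ln(0.8)/ln(R), 1 + ln(1.25)/ln(R))`;
* **Monte-Carlo virtual-population trials** (lognormal inter-individual
  variability, percentile bands, reproducible per-subject substreams);
* a **synthetic-trial generator** reproducing the ascending-dose study
  design (9 single-dose cohorts 10–300 mg, 3 multiple-dose cohorts
  60/120/200 mg Q12H × 5 days + day 6, clinical sampling schedules, LLOQ
  censoring), so everything runs with no external data.

## Worked example

```r
library(saapk)

## the acceptance bracket for a 20-300 mg dose range
acceptance_range(0.8, 1.25, dose_ratio_R = 300 / 20)
#>       low      high
#> 0.9175999 1.0824001

## simulate a single 80-mg 60-min infusion with the packaged human set
params <- default_human_params()
sim <- pbpk_simulate(params, dose_regimen(80, 1), t_end = 13)
sim
#> PBPK simulation: 80 mg x 1 (60-min infusion), 26 output times to 13 h
#>   Cmax (plasma) 2563 ng/ml; mass-balance rel. err. 5.4e-15

## full synthetic trial -> NCA -> dose proportionality
res <- pipeline_run(list(seed = 1))
res$doseprop$cmax
#> Power model [cmax]: beta = 1.208 (90% CI 1.159-1.258), n = 76
#>   acceptance range 0.918-1.082 (dose ratio R = 15)
#>   verdict: not_proportional (deviation above)
```

The verdict reproduces the study's central finding: SAA exposure rises
*more* than dose-proportionally over 20–300 mg (observed slope for Cmax:
1.214, 90% CI 1.150–1.278, against the same 0.918–1.082 range), a
nonlinearity the PBPK model attributes to saturation of hepatic
OATP1B1/P-gp transport — the packaged parameter set (calibrated to the
published cohort exposure means) shows clearance falling from ~36 L/h at
20 mg to ~20 L/h at 300 mg.

## Command line

```sh
inst/cli/saapk simulate --dose 80 --infusion-min 60 --t-end 12 --out sim.csv
inst/cli/saapk synth --seed 1 --out conc.csv
inst/cli/saapk nca --in conc.csv --out nca.csv
inst/cli/saapk doseprop --in conc.csv --out doseprop.csv
inst/cli/saapk popsim --dose 120 --n 200 --seed 42 --out pop
inst/cli/saapk run --out-dir results --seed 1
```

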