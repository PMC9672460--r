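---
title: "Methods: transporter-saturable PBPK simulation and ascending-dose PK analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transporter-saturable PBPK simulation and ascending-dose PK analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`saapk` implements the computational pipeline of a first-in-human
intravenous ascending-dose pharmacokinetic programme for salvianolic acid
A (SAA), a water-soluble phenolic acid dosed as a sodium salt by 40–60 min
infusion:

1. a whole-body, permeability-limited PBPK simulator with saturable
   hepatic transport (`pbpk_simulate()`),
2. tissue:plasma partition coefficients by the tissue-composition method
   or from distribution data (`kp_rodgers_rowland_acid()`,
   `kp_from_distribution()`),
3. non-compartmental analysis (`nca_single()`, `nca_multiple()`),
4. the power-model dose-proportionality criterion (`fit_power_model()`,
   `acceptance_range()`),
5. Monte-Carlo virtual-population trials (`run_population()`), and
6. a synthetic-trial generator reproducing the study design
   (`default_design()`, `generate_trial()`), so the whole pipeline runs
   end-to-end with no external data.

# The PBPK model

## Structure

The body is represented by venous and arterial blood pools and 14 tissue
compartments: lung, heart, brain, adipose, muscle, skin, bone, gut,
spleen, liver, kidney, reproductive organs, red marrow, and a lumped rest
of body. The lung sits in series between the venous and arterial pools
and receives total cardiac output; the remaining 13 tissues are perfused
in parallel and drain back to venous blood. Every tissue is
*permeability-limited*: it is split into a vascular sub-compartment (a
fixed fraction, default 5%, of tissue volume) and an extravascular
sub-compartment, exchanging by a permeability–surface-area product
$PS_{tc}$ (L/h) acting on unbound concentrations:

$$ J_i = PS_{tc,i}\, f_{u,b} \left( C_{vas,i} - \frac{C_{ev,i}}{K_{p,i}}
\right), $$

where $f_{u,b} = f_{u,p} / (B\!:\!P)$ is the unbound fraction referred to
blood and $K_p$ is the (total) tissue:plasma partition coefficient. Flow
terms are $Q_i (C_{art} - C_{vas,i})$. The infusion enters venous blood
as a zero-order rate $\mathrm{dose}/T_{inf}$, switched on and off at
exact event times (never smoothed), which is what keeps mass balance at
the 0.1%-of-dose level the tests demand.

## Hepatic transport and elimination

SAA is an ECCS class 3B compound (low-permeability acid, MW > 400):
clearance is dominated by transporter-mediated hepatic uptake. Two
saturable fluxes act in the liver:

* **uptake** (OATP1B1, basolateral): $v = V_{max}\,C_u/(K_m + C_u)$ on the
  unbound *vascular-side* concentration, moving drug into the hepatocyte
  pool;
* **efflux** (P-gp, canalicular): the same Michaelis–Menten form on the
  unbound *hepatocellular* concentration, routed irreversibly to an
  eliminated pool (biliary excretion without enterohepatic
  recirculation). COMT-mediated metabolism is not modelled separately but
  lumped into this hepatocellular loss; an optional linear systemic
  clearance (default 0) is retained as a residual pathway.

Both transporters share one $K_m$ by default (a single predicted constant
is all that is available for the compound); independent values can be
configured. **Unit convention:** configured $K_m$ is in ng/ml *referred to
the unbound concentration the flux acts on*. With $f_{u,p} = 0.05$, the
predicted total-plasma constant of 15,790 ng/ml (31.93 µM × 494.45 g/mol)
corresponds to ≈790 ng/ml unbound, which is the calibration starting
point.

## Why saturation explains the clinical nonlinearity

Exposure in the study rose 23.9-fold (Cmax) and 25.1-fold (AUC) for a
15-fold dose increase, with mean clearance falling from ~35 L/h (20 mg)
to ~21 L/h (300 mg). When plasma concentrations approach $K_m$, uptake
saturates, hepatic extraction falls, and dose-normalized exposure rises —
exactly the power-model slope β > 1 found clinically. The packaged
default parameter set reproduces this: simulated CL falls from 36 to
20 L/h across 20–300 mg and dose-normalized AUC is strictly increasing.

## Numerical method

The ODE system (31 states) is stiff: blood-pool turnover is of order
$CO/V \sim 10^2\,h^{-1}$ while terminal redistribution is
$\sim 10^{-1}\,h^{-1}$. No stiff integrator is available among the
package's permitted dependencies, so one is implemented in C++
(Rcpp/RcppArmadillo): a 4th-order Rosenbrock method with an embedded
3rd-order error estimate (Kaps–Rentrop, Shampine coefficients), adaptive
step control, and an *analytic* Jacobian — the system is linear except
for the two Michaelis–Menten fluxes, whose derivatives are closed-form.
Defaults: relative tolerance 1e-8, absolute tolerance 1e-3 ng, exact
breakpoints at every infusion on/off switch and output time. Verified
against the closed-form one-compartment infusion solution (< 1%
everywhere) and conservation with all sinks removed (relative error
< 1e-10). Sub-nanogram negative undershoots (below the absolute
tolerance) are clamped to zero on output.

## Partition coefficients

`kp_rodgers_rowland_acid()` implements the monoprotic-acid,
albumin-binding form of the tissue-composition equation: extracellular
water, ionization-weighted intracellular water
($X = (1+10^{pH_{iw}-pK_a})/(1+10^{pH_p-pK_a})$), neutral
lipid/phospholipid partitioning of the un-ionized fraction, and an
albumin-binding term scaled by the tissue:plasma albumin ratio; the
unbound ratio is then multiplied by $f_{u,p}$. The packaged composition
table carries standard human constants; `red_marrow` and `rest_of_body`
rows are labelled surrogates (no standard tabulation exists for lumped
compartments). For tissues with measured distribution data the
exposure-ratio route `kp_from_distribution()` is provided; the underlying
rat tissue-distribution values are in an external report and not packaged,
so the default set uses the tissue-composition route throughout.

# Default parameter set and calibration

The packaged default (`default_human_params()`) is a 70-kg adult:
reference tissue volumes, blood-flow fractions of a 390 L/h cardiac
output, and compound properties MW 494.45 g/mol, $f_{u,p}$ 0.05 (strong
plasma-protein binding typical of phenolic acids), B:P 0.6 (an acid
largely excluded from erythrocytes), pKa 2.9, logP 2.6.

Choices that were genuinely open, and how they were settled:

* **Liver blood flow.** With the prescribed series-lung/parallel-tissue
  topology there is no portal vein. A purely arterial hepatic flow
  (~6.5% CO) caps hepatic blood clearance below the observed ~35 L/h
  plasma clearance, so the liver is assigned the full splanchnic share
  (22% of CO) and gut/spleen keep nominal direct-to-venous flows. This is
  a deliberate lumping, not an anatomical claim.
* **Permeability.** $PS_{tc}$ defaults to 0.5 L/h per litre of tissue
  ("slow membrane permeation in other tissues"), then a single global
  scale is calibrated.
* **Transporter kinetics.** $K_m$ (shared), a common $V_{max}$ scale and
  the global $PS_{tc}$ scale were fitted by `calibrate_to_summaries()` —
  log least squares of deterministic simulated Cmax and AUC0-t against
  the published 20–300 mg cohort means. Result: every cohort mean within
  15% (max 13.7%), $K_m$ = 144.8 ng/ml unbound (≈2,900 ng/ml total
  plasma, i.e. "decreased" relative to the 15,790 ng/ml prediction, which
  sat above the highest observed Cmax), $V_{max}$ = 2.63×10⁸ ng/h.
* **Dose basis.** Doses are labelled mg of the injected product; no salt
  purity correction is applied, because the reference clearances were
  computed from labelled doses.

**Known limitation:** only exposure *means* are calibration targets. The
calibrated terminal half-life (~0.8 h deterministic) is shorter than the
observed 1.6–2.9 h; simulated accumulation indices (≈1.0) sit slightly
below the observed 1.08–1.17. Reproducing the terminal phase would
require the unavailable per-tissue permeability table; the published
percentile-band numbers are therefore treated as context, not targets.

# Non-compartmental analysis

Defaults follow common NCA software conventions, since the source
analysis names only the method class:

* AUC by linear-up/log-down trapezoid (plain linear by flag);
* $\lambda_z$ by log-linear regression over terminal windows of ≥ 3
  post-peak points (peak excluded), best adjusted R², window span
  required to cover ≥ 2 half-lives (violations flagged), ties toward more
  points; a non-negative slope is a flagged failure — nothing is
  extrapolated;
* $AUC_{0-\infty} = AUC_{0-t} + \hat{C}_{last}/\lambda_z$ with the
  *regression-predicted* last concentration, extrapolated fraction
  reported;
* below-LLOQ: leading values set to 0, embedded/trailing excluded;
* $CL = \mathrm{dose}/AUC_{0-\infty}$ and $V_d = CL/\lambda_z$ with fixed
  mg→ng and ml→L reconciliation (results in L/h and L);
* steady state: $C_{avg} = AUC_\tau/\tau$, fluctuation
  $(C_{max}-C_{min})/C_{avg}\times 100$, accumulation index
  $1/(1-e^{-\lambda_z \tau})$; if sampling stops short of $\tau$ the
  interval AUC is completed by log-linear extrapolation.

# Dose proportionality

The power model $\ln Y = \alpha + \beta \ln(\mathrm{dose})$ is fitted by
OLS on individual subject records (cohort-mean mode available), with a
t-based CI (default 90%). The acceptance range scales the 0.80–1.25
bioequivalence limits by the log dose ratio:
$\left(1+\frac{\ln 0.8}{\ln R}, 1+\frac{\ln 1.25}{\ln R}\right)$; for
$R = 300/20 = 15$ this is 0.918–1.082. The verdict is proportional iff
the CI lies inside the range; the deviation direction is the side of 1 on
which the CI midpoint falls when it is not. The 10-mg cohort (n = 2) is
excluded from the analysis range. No multiplicity adjustment is applied
across Cmax and AUC0-t.

# Virtual population and synthetic trials

Inter-individual variability is lognormal with the base value as median
and $\sigma^2 = \ln(1+cv^2)$. Defaults (a repository calibration, not a
reported value): cv 0.25 on transporter $V_{max}$ and tissue
permeabilities, 0.15 on cardiac output and tissue volumes. Each subject
draws independent multipliers; parallel flows are rescaled to rebalance
venous return. A master seed spawns per-subject substreams, so subject
*i* is reproducible regardless of cohort size.

The synthetic-trial generator reproduces the study design exactly: 9
single-dose cohorts (10–300 mg; 40-min infusion and 24/36-h sampling
extensions at 10 mg; 16-h extension at 120 mg; 2/6/10 active subjects and
the 5:1 placebo ratio above 20 mg) and 3 multiple-dose cohorts
(60/120/200 mg Q12H × 5 days + day-6 dose, n = 8), sampling pre-infusion,
15/30/45/60 min during infusion, and 5/10/30/45 min then 1–12 h (single
dose) or 1–10 h (multiple dose) post-infusion. Residual assay error is
multiplicative lognormal, cv 0.10 (within the stated ±15% QC band).
LLOQ censoring uses the four assay calibration ranges mapped monotonically
to dose tiers (≤20 mg → 2 ng/ml, ≤80 → 4, ≤160 → 10, else 20 ng/ml); the
cohort-to-range assignment is a package choice, as is nominal (jitter-free)
sampling time. Day-4/5 trough-only draws are not emitted (they feed no
implemented analysis). Placebo subjects appear as all-below-LLOQ profiles.

What a green test does and does not establish: the generator reproduces
the design's *first and second moments* and censoring; it assumes
independent log-normal variability (no between-parameter correlation, no
covariate effects, no dropout) and nominal sampling times, so it cannot
validate covariance structure or time-deviation robustness against the
real trial.

# Numerical and degenerate-input policy

Validation errors are classed conditions (`saapk_validation_error`)
raised before any computation; integrator failures name the failing time
span; per-subject population failures are recorded and tolerated up to 5%
of the cohort, then abort. All file writes are temp-then-rename atomic.
Optimizations are bounded on the log scale and the refit contract
guarantees the returned objective never exceeds the starting objective.

# Worked example

```{r, eval = FALSE}
library(saapk)
params <- default_human_params()
sim <- pbpk_simulate(params, dose_regimen(80, 1), t_end = 13)
res <- pipeline_run(list(seed = 1))
res$doseprop$cmax
```

Test-suite economy: stochastic checks are scaled down where the full-size
statement would dominate runtime (600 instead of 10,000 subjects for the
delta-method CV check, deterministic instead of n = 5,000 Monte-Carlo
means for calibration recovery, 40-replicate module checks with the full
200 kept in the acceptance suite); each scaled check notes this inline.
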