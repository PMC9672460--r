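# Fixture builders: small parameter sets constructed in code.

# A deliberately simple whole-body set: every tissue 1 L (muscle 5 L to
# keep some mass), uniform kp/pstc, equal flow split. Useful for oracle
# checks where physiology realism is irrelevant.
make_toy_params <- function(kp = 1, pstc = 5, vmax = 0, km = 100,
                            vmax_eff = vmax, km_eff = km,
                            clsys = 0, fu = 1, bp = 1, co = 300,
                            vven = 3, vart = 1.5) {
  nm <- tissue_names()
  vols <- ifelse(nm == "muscle", 5, 1)
  q <- rep(co / 13, 14)  # 13 parallel tissues; lung carries CO
  q[1] <- co
  tissues <- lapply(seq_along(nm), function(i)
    tissue_spec(nm[i], vols[i], q[i], kp, pstc))
  transporters <- list(
    transporter_kinetics("OATP1B1", vmax, km),
    transporter_kinetics("P-gp", vmax_eff, km_eff))
  pbpk_parameter_set(
    compound_properties("toyacid", 500, fu, bp, acid_pKa = 3, logP = 2),
    tissues, transporters, cardiac_output = co,
    venous_volume = vven, arterial_volume = vart,
    systemic_linear_clearance = clsys)
}

# Closed-form one-compartment infusion/decay concentration (ng/ml):
# zero-order rate R0 (ng/h) over [0, tinf], volume V (L), clearance CL (L/h).
one_cpt_infusion <- function(t, dose_mg, tinf, V, CL) {
  R0 <- dose_mg * 1e6 / tinf
  k <- CL / V
  css <- R0 / CL / 1000  # ng/ml
  ifelse(t <= tinf,
         css * (1 - exp(-k * t)),
         css * (1 - exp(-k * tinf)) * exp(-k * (t - tinf)))
}

# total amount in the system at the end of a simulation, ng
total_amount <- function(sim) {
  n <- length(sim$times)
  sum(sim$amounts[n, ]) + sim$eliminated[n]
}

make_profile <- function(time_h, conc, dose_mg = 100, tinf = 1,
                         tau = NA_real_, n_doses = 1L, lloq = 0,
                         occasion = "single", subject = "s1",
                         cohort = "c1") {
  concentration_time_profile(
    subject, cohort, dose_mg,
    dose_regimen(dose_mg, tinf, dosing_interval_tau = tau,
                 n_doses = n_doses),
    occasion, time_h, conc, blq = is.na(conc), lloq = lloq)
}

# terminal log-linear slope of a simulated plasma curve over [t1, t2]
sim_terminal_lambda <- function(sim, t1, t2) {
  i <- sim$times >= t1 & sim$times <= t2 & sim$plasma_conc > 0
  -unname(coef(lm(log(sim$plasma_conc[i]) ~ sim$times[i]))[2])
}
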