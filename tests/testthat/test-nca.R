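test_that("trapezoidal AUC matches closed forms", {
  # constant concentration
  pr <- make_profile(c(0, 1, 2), c(100, 100, 100))
  expect_equal(compute_auc(pr, method = "linear"), 200)
  # dense mono-exponential vs analytic integral
  t <- seq(0, 10, by = 0.01)
  pr2 <- make_profile(t, 1000 * exp(-0.5 * t))
  analytic <- 1000 / 0.5 * (1 - exp(-5))
  expect_lt(abs(compute_auc(pr2, method = "linear") - analytic) / analytic,
            0.005)
  # log-trapezoid closed form on a single declining interval
  pr3 <- make_profile(c(1, 2), c(100, 50))
  expect_equal(compute_auc(pr3, method = "linear_up_log_down"),
               100 * (1 - 0.5) / log(2), tolerance = 1e-12)
})

test_that("AUC is additive over intervals and monotone in t_end", {
  t <- c(0, 0.5, 1, 2, 3, 5, 8)
  pr <- make_profile(t, c(0, 800, 1000, 600, 350, 120, 20))
  for (m in c("linear", "linear_up_log_down")) {
    whole <- compute_auc(pr, t_end = 8, method = m)
    parts <- compute_auc(pr, t_end = 3, method = m) +
      (whole - compute_auc(pr, t_end = 3, method = m))
    expect_equal(whole, parts)
    aucs <- vapply(c(1, 2, 3, 5, 8), function(te)
      compute_auc(pr, t_end = te, method = m), numeric(1))
    expect_true(all(diff(aucs) > 0))
  }
  expect_error(compute_auc(pr, t_end = 0.2), "t_end")
})

test_that("terminal slope is exact on log-linear data", {
  t <- c(4, 6, 8, 10, 12)
  pr <- make_profile(c(0.5, 1, t), c(200, 1500, 1000 * exp(-0.3466 * t)))
  lz <- estimate_lambda_z(pr)
  expect_equal(lz$lambda_z, 0.3466, tolerance = 1e-10)
  expect_equal(log(2) / lz$lambda_z, 2.0, tolerance = 1e-3)
  expect_true(lz$span_ok)
})

test_that("terminal slope recovers the slow phase of a biphasic profile", {
  t <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12)
  conc <- 5000 * exp(-2 * t) + 500 * exp(-0.2 * t)
  pr <- make_profile(t, conc)
  lz <- estimate_lambda_z(pr)
  expect_lt(abs(lz$lambda_z - 0.2) / 0.2, 0.02)
})

test_that("flat or rising terminal data are flagged, not extrapolated", {
  pr <- make_profile(c(1, 2, 4, 6, 8), c(1000, 50, 50, 50, 50))
  lz <- estimate_lambda_z(pr)
  expect_true(is.na(lz$lambda_z))
  expect_match(lz$reason, "slope")
  r <- nca_single(pr)
  expect_true(is.na(r$auc_inf) && is.na(r$cl) && is.na(r$vd))
  expect_false(is.na(r$auc_last))
})

test_that("single-dose NCA recovers one-compartment truth", {
  # 80 mg over 60 min, CL = 30 L/h, V = 100 L; clinical sampling schedule
  sched <- c(0.25, 0.5, 0.75, 1, 1 + 5 / 60, 1 + 10 / 60, 1.5, 1.75,
             2, 2.5, 3, 4, 5, 7, 9, 11, 13)
  conc <- one_cpt_infusion(sched, 80, 1, V = 100, CL = 30)
  pr <- make_profile(sched, conc, dose_mg = 80)
  r <- nca_single(pr)
  expect_lt(abs(r$cl - 30) / 30, 0.05)
  expect_lt(abs(r$vd - 100) / 100, 0.08)
  expect_lt(abs(r$t_half - log(2) / 0.3) / (log(2) / 0.3), 0.05)
  expect_gte(r$auc_inf, r$auc_last)
})

test_that("NCA scale equivariance", {
  sched <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12)
  conc <- one_cpt_infusion(sched, 50, 1, V = 80, CL = 25)
  base <- nca_single(make_profile(sched, conc, dose_mg = 50))
  scaled <- nca_single(make_profile(sched, conc * 10, dose_mg = 50))
  expect_equal(scaled$cmax, base$cmax * 10)
  expect_equal(scaled$auc_last, base$auc_last * 10)
  expect_equal(scaled$t_half, base$t_half)
  expect_equal(scaled$cl, base$cl / 10)
  expect_equal(scaled$vd, base$vd / 10)
})

test_that("below-limit samples are zeroed before tmax and dropped after", {
  t <- c(0, 0.5, 1, 2, 4, 6, 8, 10)
  conc <- c(NA, 400, 900, 500, 120, 30, NA, NA)
  pr <- make_profile(t, conc, lloq = 10)
  r <- nca_single(pr)
  # leading BLQ contributes a zero anchor; trailing BLQ are excluded
  expect_equal(r$auc_last, compute_auc(pr))
  expect_equal(r$cmax, 900)
  pr_all_blq <- make_profile(c(0, 1, 2), c(NA, NA, NA), lloq = 10)
  expect_error(nca_single(pr_all_blq), "quantifiable")
})

test_that("steady-state NCA implements the interval formulas", {
  # accumulation index at lambda_z = ln2/3 and tau = 12: 1/(1-2^-4)
  t <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12)
  lz <- log(2) / 3
  conc <- 3000 * exp(-lz * t)
  pr <- make_profile(t, conc, dose_mg = 60, tau = 12, n_doses = 11L,
                     occasion = "day6")
  r <- nca_multiple(pr)
  expect_equal(r$accumulation_index, 16 / 15, tolerance = 1e-6)
  expect_equal(r$cavg, r$auc_tau / 12)
  # fluctuation on a hand-made triple
  expect_equal((200 - 40) / 80 * 100, 200)
  expect_equal(r$fluctuation_pct, (r$cmax - r$cmin) / r$cavg * 100)
  # tau required
  pr_no_tau <- make_profile(t, conc, dose_mg = 60)
  expect_error(nca_multiple(pr_no_tau), "tau")
})

test_that("day-6 accumulation matches the simulated terminal slope", {
  p <- make_toy_params(vmax = 0, clsys = 15)  # linear kinetics
  tau <- 12
  reg <- dose_regimen(60, 1, dosing_interval_tau = tau, n_doses = 11L)
  day6 <- (11 - 1) * tau
  sched <- c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 3, 4, 6, 8, 10, 11.9)
  grid <- sort(unique(c(day6 + sched, seq(1, 132, by = 0.5))))
  sim <- pbpk_simulate(p, reg, 132, output_grid = grid)
  conc <- sim_plasma_at(sim, day6 + sched)
  pr <- make_profile(sched, conc, dose_mg = 60, tau = tau, n_doses = 11L,
                     occasion = "day6")
  r <- nca_multiple(pr)
  lz_sim <- sim_terminal_lambda(
    pbpk_simulate(p, dose_regimen(60, 1), 40,
                  output_grid = seq(0.5, 40, 0.5)), 20, 40)
  expect_lt(abs(r$accumulation_index - 1 / (1 - exp(-lz_sim * tau))) /
              (1 / (1 - exp(-lz_sim * tau))), 0.02)
})

test_that("cohort mean Cmax ratio across the dose extremes is ~23.9", {
  s <- sad_reference_summaries()
  ratio <- s$cmax_mean[s$dose_mg == 300] / s$cmax_mean[s$dose_mg == 20]
  expect_equal(round(ratio, 1), 23.9)
})

test_that("nca_table dispatches occasions and skips placebo", {
  sched <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8, 10, 12)
  conc <- one_cpt_infusion(sched, 60, 1, 90, 28)
  single <- make_profile(sched, conc, dose_mg = 60, subject = "a")
  day6 <- make_profile(sched, conc, dose_mg = 60, tau = 12, n_doses = 11L,
                       occasion = "day6", subject = "b")
  placebo <- make_profile(sched, rep(NA_real_, length(sched)),
                          dose_mg = 60, subject = "p", lloq = 2)
  tab <- nca_table(list(single, day6, placebo))
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$auc_tau[tab$subject_id == "a"]))
  expect_false(is.na(tab$auc_tau[tab$subject_id == "b"]))
})
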