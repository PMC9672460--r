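test_that("default design mirrors the ascending-dose study layout", {
  d <- default_design()
  single <- d$cohorts[d$cohorts$regimen_type == "single", ]
  multi <- d$cohorts[d$cohorts$regimen_type == "q12h_6day", ]
  expect_equal(nrow(single), 9)
  expect_equal(nrow(multi), 3)
  expect_setequal(single$dose_mg,
                  c(10, 20, 40, 80, 120, 160, 200, 250, 300))
  expect_setequal(multi$dose_mg, c(60, 120, 200))
  expect_equal(single$infusion_min[single$dose_mg == 10], 40)
  expect_true(all(single$infusion_min[single$dose_mg != 10] == 60))
  expect_equal(sum(single$n_active), 78)   # dosed subjects, part A
  expect_equal(sum(single$n_placebo), 14)
  expect_true(all(multi$n_active == 8))
})

test_that("sampling schedules carry the printed extensions", {
  d <- default_design()
  for (s in d$schedules) expect_true(all(diff(s) > 0))
  # 40-min infusion cohort: in-infusion draws at 10/20/30/40 min and
  # post-infusion extensions at 24 and 36 h
  sg0 <- d$schedules$SG0
  expect_true(all((c(10, 20, 30, 40) / 60) %in% sg0))
  expect_true(all((40 / 60 + c(24, 36)) %in% sg0))
  # 120-mg cohort: extra 16-h post-infusion draw
  expect_true(17 %in% d$schedules$SG4)
  # standard single-dose schedule ends 12 h post-infusion
  expect_equal(max(d$schedules$SG1), 13)
  # multiple-dose occasions sampled to 10 h post-infusion
  expect_equal(max(d$schedules$RG1), 11)
})

test_that("assay LLOQ tiers are monotone in dose", {
  d <- default_design()
  sg <- d$cohorts[d$cohorts$regimen_type == "single", ]
  sg <- sg[order(sg$dose_mg), ]
  expect_true(all(diff(sg$lloq) >= 0))
  expect_setequal(unique(d$cohorts$lloq), c(2, 4, 10, 20))
})

# a two-cohort slice of the design keeps generator tests fast
small_design <- function() {
  d <- default_design()
  d$cohorts <- d$cohorts[d$cohorts$cohort_id %in% c("SG1", "SG8"), ]
  d$schedules <- d$schedules[c("SG1", "SG8")]
  d
}

test_that("trial generation is seed-deterministic and censors below LLOQ", {
  p <- default_human_params()
  d <- small_design()
  a <- generate_trial(d, p, seed = 21)
  b <- generate_trial(d, p, seed = 21)
  expect_equal(length(a), sum(d$cohorts$n_active + d$cohorts$n_placebo))
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  c2 <- generate_trial(d, p, seed = 22)
  expect_false(identical(lapply(a, `[[`, "samples"),
                         lapply(c2, `[[`, "samples")))
  for (pr in a) {
    expect_s3_class(pr, "conc_profile")
    q <- pr$samples
    expect_true(all(is.na(q$conc_ng_ml[q$blq])))
    expect_true(all(q$conc_ng_ml[!q$blq] >= pr$lloq))
  }
})

test_that("zero variability makes cohort subjects identical", {
  p <- default_human_params()
  d <- small_design()
  d$cohorts <- d$cohorts[d$cohorts$cohort_id == "SG1", ]
  d$schedules <- d$schedules["SG1"]
  profs <- generate_trial(d, p, variability = list(),
                          residual_cv = 0, seed = 1)
  act <- Filter(function(x) is.null(x$treatment), profs)
  for (i in seq_along(act)[-1])
    expect_equal(act[[i]]$samples$conc_ng_ml, act[[1]]$samples$conc_ng_ml)
})

test_that("placebo subjects are emitted as all-below-limit profiles", {
  p <- default_human_params()
  d <- default_design()
  d$cohorts <- d$cohorts[d$cohorts$cohort_id == "SG3", ]
  d$schedules <- d$schedules["SG3"]
  profs <- generate_trial(d, p, seed = 2)
  plc <- Filter(function(x) identical(x$treatment, "placebo"), profs)
  expect_length(plc, 2)
  for (pr in plc) expect_true(all(pr$samples$blq))
})

test_that("multiple-dose cohorts yield day-1 and day-6 occasions", {
  p <- default_human_params()
  d <- default_design()
  d$cohorts <- d$cohorts[d$cohorts$cohort_id == "RG1", ]
  d$cohorts$n_active <- 2L
  d$schedules <- d$schedules["RG1"]
  profs <- generate_trial(d, p, seed = 3)
  occ <- vapply(profs, `[[`, character(1), "occasion")
  expect_equal(sum(occ == "day1"), 2)
  expect_equal(sum(occ == "day6"), 2)
  d6 <- profs[[which(occ == "day6")[1]]]
  expect_lte(max(d6$samples$time_h), 12)   # relative to the day-6 dose
  expect_equal(d6$regimen$n_doses, 11L)
})

test_that("generated trials reproduce the generator's Cmax fold change", {
  p <- default_human_params()
  d <- small_design()
  # anchor: the generator's own large-cohort mean ratio (the design's
  # n = 6/10 cohorts carry ~10% sampling noise per trial, so replicate
  # trials are averaged and compared against a 40-subject-per-cohort run)
  big <- d
  big$cohorts$n_active <- 40L
  big$cohorts$n_placebo <- 0L
  btab <- nca_table(generate_trial(big, p, seed = 301))
  anchor <- mean(btab$cmax[btab$dose_mg == 300]) /
    mean(btab$cmax[btab$dose_mg == 20])
  ratios <- vapply(c(31, 32, 33), function(sd) {
    tab <- nca_table(generate_trial(d, p, seed = sd))
    mean(tab$cmax[tab$dose_mg == 300]) / mean(tab$cmax[tab$dose_mg == 20])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - anchor) / anchor, 0.10)
  # and the fold change itself is in the strongly supra-proportional
  # regime the truth was calibrated to (15-fold doses, >20-fold exposure)
  expect_gt(mean(ratios), 15)
})

test_that("calibration self-test accepts generator-produced targets", {
  p <- default_human_params()
  doses <- c(20, 80, 300)
  sched <- default_design()$schedules$SG1
  targets <- do.call(rbind, lapply(doses, function(dd) {
    sim <- pbpk_simulate(p, dose_regimen(dd, 1), 13.001,
                         output_grid = c(sched, 13.001))
    conc <- sim_plasma_at(sim, sched)
    pr <- make_profile(sched, conc, dose_mg = dd)
    r <- nca_single(pr)
    data.frame(cohort_id = sprintf("d%g", dd), dose_mg = dd,
               parameter_name = c("cmax", "auc_last"),
               mean = c(r$cmax, r$auc_last), sd = c(r$cmax, r$auc_last) * 0.15)
  }))
  cal <- calibrate_to_summaries(targets, p, maxit = 5)
  expect_true(cal$feasible)
  expect_true(all(cal$fit <= 0.15))
  expect_equal(cal$residual_cv, 0.10)
})

test_that("packaged defaults reproduce published 20-300 mg means within 15%", {
  p <- default_human_params()
  design <- default_design()
  sched <- design$schedules$SG1
  tg <- summary_targets()
  for (d in unique(tg$dose_mg)) {
    sim <- pbpk_simulate(p, dose_regimen(d, 1), 13.001,
                         output_grid = c(sched, 13.001))
    conc <- sim_plasma_at(sim, sched)
    # censor at the cohort's assay LLOQ, as the observed AUC0-t was
    lloq <- design$cohorts$lloq[design$cohorts$dose_mg == d &
                                  design$cohorts$regimen_type == "single"]
    r <- nca_single(make_profile(
      sched, ifelse(conc < lloq, NA_real_, conc), dose_mg = d,
      lloq = lloq))
    for (pn in c("cmax", "auc_last")) {
      target <- tg$mean[tg$dose_mg == d & tg$parameter_name == pn]
      expect_lt(abs(r[[pn]] - target) / target, 0.15,
                label = sprintf("%s at %g mg rel.err.", pn, d))
    }
  }
})
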