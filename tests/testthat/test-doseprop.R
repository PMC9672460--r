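test_that("acceptance range follows the log-scaled bioequivalence bracket", {
  rng <- acceptance_range(0.8, 1.25, 15)
  expect_equal(round(unname(rng), 3), c(0.918, 1.082))
  # ln(R) = 1 makes the bracket 1 + ln(theta)
  rng_e <- acceptance_range(0.8, 1.25, exp(1))
  expect_equal(unname(rng_e), c(1 + log(0.8), 1 + log(1.25)),
               tolerance = 1e-12)
  # antisymmetric limits give a range symmetric about 1
  rng_s <- acceptance_range(0.8, 1.25, 7)
  expect_equal(rng_s[["high"]] - 1, 1 - rng_s[["low"]], tolerance = 1e-12)
  expect_error(acceptance_range(0.8, 1.25, 1), "dose_ratio_R")
  expect_error(acceptance_range(1.1, 1.25, 5), "theta")
})

test_that("exact power laws are fitted exactly", {
  recs <- data.frame(subject_id = letters[1:6],
                     dose = rep(c(20, 40, 80), 2))
  recs$value <- 7 * recs$dose
  fit <- fit_power_model(recs)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_equal(fit$verdict, "proportional")
  expect_equal(fit$deviation_direction, "none")

  # quadratic law; two doses rejected, three fitted exactly
  two <- data.frame(subject_id = c("a", "b"), dose = c(10, 100),
                    value = c(10, 1000))
  expect_error(fit_power_model(two), "3 distinct dose")
  three <- rbind(two, data.frame(subject_id = "c", dose = 1000,
                                 value = 1e5))
  expect_equal(fit_power_model(three)$beta, 2, tolerance = 1e-12)
})

test_that("slope equals the hand-computed OLS solution", {
  # doses {1, e, e^2}; ln Y = {0, 1.1, 2.3}: Sxy/Sxx = 2.3/2 = 1.15
  recs <- data.frame(subject_id = c("a", "b", "c"),
                     dose = exp(0:2), value = exp(c(0, 1.1, 2.3)))
  expect_equal(fit_power_model(recs)$beta, 1.15, tolerance = 1e-12)
})

test_that("beta is invariant to value and dose rescaling", {
  set.seed(11)
  recs <- data.frame(subject_id = as.character(1:30),
                     dose = rep(c(20, 80, 300), 10))
  recs$value <- recs$dose^1.2 * exp(rnorm(30, 0, 0.2))
  base <- fit_power_model(recs)
  v10 <- recs; v10$value <- v10$value * 10
  expect_equal(fit_power_model(v10)$beta, base$beta, tolerance = 1e-12)
  expect_equal(fit_power_model(v10)$alpha, base$alpha + log(10),
               tolerance = 1e-10)
  dmu <- recs; dmu$dose <- dmu$dose * 1000  # mg -> ug
  expect_equal(fit_power_model(dmu)$beta, base$beta, tolerance = 1e-12)
})

test_that("narrowing the CI never rescues a non-proportional verdict", {
  set.seed(12)
  recs <- data.frame(subject_id = as.character(1:24),
                     dose = rep(c(20, 60, 150, 300), 6))
  recs$value <- recs$dose^1.25 * exp(rnorm(24, 0, 0.15))
  wide <- fit_power_model(recs, ci_level = 0.95)
  narrow <- fit_power_model(recs, ci_level = 0.80)
  if (wide$verdict == "not_proportional" &&
      wide$beta > wide$acceptance_range[["high"]])
    expect_equal(narrow$verdict, "not_proportional")
  expect_lt(narrow$beta_ci[2] - narrow$beta_ci[1],
            wide$beta_ci[2] - wide$beta_ci[1])
})

test_that("cohort-mean mode and per-parameter dispatch work", {
  recs <- rbind(
    data.frame(subject_id = as.character(1:9),
               dose = rep(c(20, 80, 300), 3), parameter_name = "cmax",
               value = rep(c(20, 80, 300), 3)^1.1),
    data.frame(subject_id = as.character(1:9),
               dose = rep(c(20, 80, 300), 3), parameter_name = "auc_last",
               value = rep(c(20, 80, 300), 3)^0.95))
  res <- dose_proportionality(recs)
  expect_named(res, c("auc_last", "cmax"))
  expect_equal(res$cmax$beta, 1.1, tolerance = 1e-10)
  means <- fit_power_model(recs[recs$parameter_name == "cmax", ],
                           use_cohort_means = TRUE)
  expect_equal(means$beta, 1.1, tolerance = 1e-10)
})

test_that("summary-driven replicate trials reproduce the study verdict", {
  tr <- simulate_summary_trials("cmax", n_trials = 40, seed = 99)
  expect_equal(nrow(tr), 40)
  expect_lt(abs(mean(tr$beta) - 1.21), 0.04)
  expect_gte(mean(tr$verdict == "not_proportional" &
                    tr$deviation_direction == "above"), 0.95)
})
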