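# Dose-proportionality assessment by the power model
# ln(Y) = alpha + beta * ln(dose), with the bioequivalence-scaled
# acceptance range for the slope.

#' Acceptance range for the power-model slope
#'
#' Scales the bioequivalence limits by the log of the dose ratio:
#' `(1 + ln(theta_low)/ln(R), 1 + ln(theta_high)/ln(R))`, where `R` is the
#' ratio of the highest to the lowest dose studied.
#'
#' @param theta_low,theta_high bioequivalence limits, `0 < theta_low < 1 <
#'   theta_high` (conventionally 0.8 and 1.25).
#' @param dose_ratio_R highest/lowest dose ratio, > 1.
#' @return Numeric vector `c(low, high)` straddling 1.
#' @export
acceptance_range <- function(theta_low = 0.8, theta_high = 1.25,
                             dose_ratio_R) {
  .chk(is.finite(theta_low) && is.finite(theta_high) &&
         theta_low > 0 && theta_low < 1 && theta_high > 1,
       "need 0 < theta_low < 1 < theta_high")
  .chk(is.finite(dose_ratio_R) && dose_ratio_R > 1,
       "dose_ratio_R must be > 1")
  c(low = 1 + log(theta_low) / log(dose_ratio_R),
    high = 1 + log(theta_high) / log(dose_ratio_R))
}

#' Fit the power model and judge dose proportionality
#'
#' Ordinary least squares of `ln(value)` on `ln(dose)` over individual
#' subject records (or cohort means with `use_cohort_means = TRUE`), with a
#' t-distribution confidence interval for the slope. Exposure is declared
#' dose-proportional iff the whole CI lies inside the acceptance range.
#'
#' @param records data.frame with columns `subject_id`, `dose`, `value`
#'   (one pharmacokinetic parameter; optional `parameter_name` column must
#'   be constant).
#' @param ci_level confidence level for the slope (default 0.90).
#' @param theta_low,theta_high bioequivalence limits for
#'   [acceptance_range()].
#' @param use_cohort_means fit on per-dose mean values instead of
#'   individual records.
#' @return An object of class `doseprop_result`: `alpha`, `beta`,
#'   `beta_ci`, `acceptance_range`, `dose_ratio_R`, `verdict`
#'   (`"proportional"`/`"not_proportional"`), `deviation_direction`
#'   (`"above"`, `"below"`, `"none"`), `n`, `ci_level`.
#' @export
fit_power_model <- function(records, ci_level = 0.90, theta_low = 0.8,
                            theta_high = 1.25, use_cohort_means = FALSE) {
  .chk(is.data.frame(records) && all(c("dose", "value") %in% names(records)),
       "records must have columns dose and value")
  if ("parameter_name" %in% names(records))
    .chk(length(unique(records$parameter_name)) == 1,
         "records must cover a single parameter; see dose_proportionality()")
  .chk(all(records$dose > 0) && all(records$value > 0),
       "doses and values must be > 0")
  .chk(ci_level > 0 && ci_level < 1, "ci_level must lie in (0, 1)")
  .chk(length(unique(records$dose)) >= 3,
       "need >= 3 distinct dose levels to fit the power model")

  if (use_cohort_means) {
    agg <- stats::aggregate(value ~ dose, records, mean)
    x <- log(agg$dose); y <- log(agg$value)
  } else {
    x <- log(records$dose); y <- log(records$value)
  }
  n <- length(x)
  fit <- lm(y ~ x)
  beta <- coef(fit)[["x"]]
  alpha <- coef(fit)[["(Intercept)"]]
  se <- suppressWarnings(summary(fit)$coefficients["x", "Std. Error"])
  tcrit <- qt(1 - (1 - ci_level) / 2, df = n - 2)
  ci <- c(beta - tcrit * se, beta + tcrit * se)

  R <- max(records$dose) / min(records$dose)
  rng <- acceptance_range(theta_low, theta_high, R)
  contained <- ci[1] >= rng[["low"]] && ci[2] <= rng[["high"]]
  mid <- mean(ci)
  structure(list(
    alpha = alpha, beta = beta, beta_ci = ci, ci_level = ci_level,
    acceptance_range = rng, dose_ratio_R = R,
    verdict = if (contained) "proportional" else "not_proportional",
    deviation_direction = if (contained) "none"
      else if (mid > 1) "above" else if (mid < 1) "below" else "none",
    n = n,
    parameter_name = if ("parameter_name" %in% names(records))
      records$parameter_name[1] else NA_character_),
    class = "doseprop_result")
}

#' Dose-proportionality assessment for each parameter in a record table
#'
#' @param records data.frame with columns `subject_id`, `dose`,
#'   `parameter_name`, `value`.
#' @param ... passed to [fit_power_model()].
#' @return Named list of `doseprop_result`, one per parameter.
#' @export
dose_proportionality <- function(records, ...) {
  .chk(is.data.frame(records) &&
         all(c("dose", "parameter_name", "value") %in% names(records)),
       "records must have columns dose, parameter_name, value")
  lapply(split(records, records$parameter_name), fit_power_model, ...)
}

#' @export
print.doseprop_result <- function(x, ...) {
  cat(sprintf("Power model%s: beta = %.3f (%.0f%% CI %.3f-%.3f), n = %d\n",
              if (is.na(x$parameter_name)) ""
              else sprintf(" [%s]", x$parameter_name),
              x$beta, 100 * x$ci_level, x$beta_ci[1], x$beta_ci[2], x$n))
  cat(sprintf("  acceptance range %.3f-%.3f (dose ratio R = %.3g)\n",
              x$acceptance_range[["low"]], x$acceptance_range[["high"]],
              x$dose_ratio_R))
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (x$deviation_direction == "none") ""
              else sprintf(" (deviation %s)", x$deviation_direction)))
  invisible(x)
}

#' Replicate power-model trials drawn from published cohort summaries
#'
#' Emulates the single ascending-dose trial at the summary level: for each
#' cohort, per-subject parameter values are drawn lognormally so that the
#' arithmetic mean and SD match the published summaries at the published
#' group sizes, then the power model is fitted. Repeated over `n_trials`
#' independent trials.
#'
#' @param parameter `"cmax"` or `"auc_last"`.
#' @param n_trials number of replicate trials.
#' @param seed integer seed.
#' @param doses dose levels included (default 20-300 mg, the
#'   dose-proportionality analysis range; the n = 2 10-mg cohort is
#'   excluded).
#' @param summaries cohort summary table, by default
#'   [sad_reference_summaries()].
#' @param ... passed to [fit_power_model()].
#' @return data.frame with one row per trial: `beta`, `ci_low`, `ci_high`,
#'   `verdict`, `deviation_direction`.
#' @export
simulate_summary_trials <- function(parameter = c("cmax", "auc_last"),
                                    n_trials = 200, seed = 1,
                                    doses = c(20, 40, 80, 120, 160, 200,
                                              250, 300),
                                    summaries = sad_reference_summaries(),
                                    ...) {
  parameter <- match.arg(parameter)
  s <- summaries[summaries$dose_mg %in% doses, ]
  m <- s[[paste0(parameter, "_mean")]]
  sdv <- s[[paste0(parameter, "_sd")]]
  cv <- sdv / m
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2   # matches the arithmetic mean
  set.seed(seed)
  out <- lapply(seq_len(n_trials), function(k) {
    recs <- do.call(rbind, lapply(seq_len(nrow(s)), function(i)
      data.frame(subject_id = sprintf("t%d-%s-%d", k, s$cohort_id[i],
                                      seq_len(s$n[i])),
                 dose = s$dose_mg[i],
                 value = rlnorm(s$n[i], meanlog[i], sdlog[i]))))
    fit <- fit_power_model(recs, ...)
    data.frame(beta = fit$beta, ci_low = fit$beta_ci[1],
               ci_high = fit$beta_ci[2], verdict = fit$verdict,
               deviation_direction = fit$deviation_direction)
  })
  do.call(rbind, out)
}
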