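# Non-compartmental analysis.
#
# Below-LLOQ handling (standard practice): flagged samples before the first
# quantifiable concentration are set to zero; embedded and trailing flagged
# samples are excluded from all calculations.

.nca_series <- function(profile) {
  s <- profile$samples
  pos <- which(!s$blq & s$conc_ng_ml > 0)
  if (length(pos) == 0) return(data.frame(time_h = numeric(0),
                                          conc = numeric(0)))
  # quantifiable samples (explicit zeros included, e.g. pre-dose draws);
  # flagged samples before the first positive value anchor at zero
  qidx <- which(!s$blq)
  keep <- s$blq & seq_len(nrow(s)) < min(pos)
  out <- data.frame(time_h = c(s$time_h[keep], s$time_h[qidx]),
                    conc = c(rep(0, sum(keep)), s$conc_ng_ml[qidx]))
  out[order(out$time_h), ]
}

# trapezoid over one interval
.auc_interval <- function(t1, t2, c1, c2, method) {
  dt <- t2 - t1
  if (method == "linear_up_log_down" && c2 < c1 && c2 > 0 && c1 > 0)
    (c1 - c2) / log(c1 / c2) * dt
  else
    (c1 + c2) / 2 * dt
}

#' Area under a concentration-time curve
#'
#' Trapezoidal AUC with either the plain linear rule or the
#' linear-up/log-down rule (log-trapezoid on declining segments, the common
#' NCA convention and this package's default elsewhere).
#'
#' @param profile a [concentration_time_profile()].
#' @param t_end upper limit, h; must not precede the second quantifiable
#'   sample. Interpolated (by the active rule) if between samples.
#' @param method `"linear"` or `"linear_up_log_down"`.
#' @return AUC in h*ng/ml.
#' @export
compute_auc <- function(profile, t_end = NULL,
                        method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  ser <- .nca_series(profile)
  .chk(nrow(ser) >= 2, "need >= 2 quantifiable samples")
  if (is.null(t_end)) t_end <- max(ser$time_h)
  .chk(t_end >= ser$time_h[2], "t_end precedes the second sample")
  .chk(t_end <= max(ser$time_h), "t_end beyond last quantifiable sample")
  auc <- 0
  for (i in seq_len(nrow(ser) - 1)) {
    t1 <- ser$time_h[i]; t2 <- ser$time_h[i + 1]
    if (t1 >= t_end) break
    c1 <- ser$conc[i]; c2 <- ser$conc[i + 1]
    if (t2 > t_end) {  # partial interval: interpolate at t_end
      c2 <- .interp_conc(t1, t2, c1, c2, t_end, method)
      t2 <- t_end
    }
    auc <- auc + .auc_interval(t1, t2, c1, c2, method)
  }
  auc
}

.interp_conc <- function(t1, t2, c1, c2, t, method) {
  if (method == "linear_up_log_down" && c2 < c1 && c2 > 0 && c1 > 0)
    exp(log(c1) + (log(c2) - log(c1)) * (t - t1) / (t2 - t1))
  else
    c1 + (c2 - c1) * (t - t1) / (t2 - t1)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression over terminal windows of at least three
#' quantifiable post-peak samples (the peak itself excluded). Among
#' windows whose time span covers at least twice the implied half-life the
#' one with the highest adjusted R-squared wins, ties broken toward more
#' points; if no window satisfies the span rule the best window is
#' returned with `span_ok = FALSE`.
#'
#' @param profile a [concentration_time_profile()].
#' @return List with `lambda_z` (1/h), `n_points`, `r2adj`, `intercept`
#'   (log ng/ml), `clast_pred` (regression-predicted concentration at the
#'   last quantifiable time), `span_ok`. A non-negative terminal slope is a
#'   flagged failure: `lambda_z = NA` and `reason` is set.
#' @export
estimate_lambda_z <- function(profile) {
  ser <- .nca_series(profile)
  ser <- ser[ser$conc > 0, ]
  fail <- function(reason) list(lambda_z = NA_real_, n_points = NA_integer_,
                                r2adj = NA_real_, intercept = NA_real_,
                                clast_pred = NA_real_, span_ok = FALSE,
                                reason = reason)
  if (nrow(ser) < 3) return(fail("fewer than 3 quantifiable samples"))
  imax <- which.max(ser$conc)
  term <- ser[seq_len(nrow(ser)) > imax, ]   # strictly after the peak
  n <- nrow(term)
  if (n < 3) return(fail("fewer than 3 post-peak samples"))

  t_last <- term$time_h[n]
  cand <- list()
  for (start in seq_len(n - 2)) {
    w <- term[start:n, ]
    fit <- lm(log(conc) ~ time_h, data = w)
    slope <- coef(fit)[["time_h"]]
    y <- log(w$conc)
    sst <- sum((y - mean(y))^2)
    # flat data fit with slope ~ -1e-17 of rounding noise: not a decline
    if (sst == 0 || slope >= -1e-12) next
    k <- nrow(w)
    # adjusted R-squared computed directly (summary() warns on exact fits)
    sse <- sum(residuals(fit)^2)
    r2 <- 1 - (sse / sst) * (k - 1) / (k - 2)
    lz <- -slope
    span_ok <- (w$time_h[k] - w$time_h[1]) >= 2 * log(2) / lz
    cand[[length(cand) + 1]] <- list(
      lambda_z = lz, n_points = k, r2adj = r2,
      intercept = coef(fit)[["(Intercept)"]],
      clast_pred = exp(coef(fit)[["(Intercept)"]] + slope * t_last),
      span_ok = span_ok, reason = NA_character_)
  }
  if (length(cand) == 0) return(fail("no window with negative slope"))
  ok <- Filter(function(z) z$span_ok, cand)
  pool <- if (length(ok)) ok else cand
  r2s <- vapply(pool, `[[`, numeric(1), "r2adj")
  nps <- vapply(pool, `[[`, numeric(1), "n_points")
  # best adjusted R-squared; ties (within 1e-4) toward more points
  best <- which(r2s >= max(r2s) - 1e-4)
  pool[[best[which.max(nps[best])]]]
}

.nca_skeleton <- function() {
  list(cmax = NA_real_, tmax = NA_real_, auc_last = NA_real_,
       auc_inf = NA_real_, auc_tau = NA_real_, lambda_z = NA_real_,
       lambda_z_n_points = NA_integer_, lambda_z_r2adj = NA_real_,
       t_half = NA_real_, cl = NA_real_, vd = NA_real_, cavg = NA_real_,
       cmin = NA_real_, fluctuation_pct = NA_real_,
       accumulation_index = NA_real_, extrapolated_fraction = NA_real_,
       lambda_z_reason = NA_character_)
}

#' Single-dose non-compartmental analysis
#'
#' Computes Cmax, Tmax, AUC to the last quantifiable sample, AUC
#' extrapolated to infinity (using the regression-predicted last
#' concentration), terminal half-life, clearance and apparent volume of
#' distribution. Units: CL in L/h and Vd in L (dose mg, concentrations
#' ng/ml; the mg-to-ng and ml-to-L factors are applied internally).
#'
#' @param profile a [concentration_time_profile()] (single-dose occasion).
#' @param auc_method passed to [compute_auc()].
#' @return An object of class `nca_result`. When the terminal-slope fit
#'   fails, `auc_inf`, `cl`, `vd` and `t_half` are `NA` and
#'   `lambda_z_reason` explains why.
#' @export
nca_single <- function(profile,
                       auc_method = c("linear_up_log_down", "linear")) {
  auc_method <- match.arg(auc_method)
  .chk(inherits(profile, "conc_profile"), "invalid profile")
  ser <- .nca_series(profile)
  .chk(nrow(ser) >= 2 && any(ser$conc > 0),
       sprintf("no quantifiable concentrations for subject %s",
               profile$subject_id))
  out <- .nca_skeleton()
  imax <- which.max(ser$conc)
  out$cmax <- ser$conc[imax]
  out$tmax <- ser$time_h[imax]
  out$auc_last <- compute_auc(profile, method = auc_method)

  lz <- estimate_lambda_z(profile)
  out$lambda_z <- lz$lambda_z
  out$lambda_z_n_points <- lz$n_points
  out$lambda_z_r2adj <- lz$r2adj
  if (!is.na(lz$lambda_z)) {
    extrap <- lz$clast_pred / lz$lambda_z
    out$auc_inf <- out$auc_last + extrap
    out$extrapolated_fraction <- extrap / out$auc_inf
    out$t_half <- log(2) / lz$lambda_z
    # dose mg -> ng (x1e6); AUC h*ng/ml -> h*ng/L (x1e3); CL in L/h
    out$cl <- profile$dose_mg * 1e3 / out$auc_inf
    out$vd <- out$cl / lz$lambda_z
  } else {
    out$lambda_z_reason <- lz$reason
  }
  structure(c(list(subject_id = profile$subject_id,
                   cohort_id = profile$cohort_id,
                   dose_mg = profile$dose_mg,
                   occasion = profile$occasion), out),
            class = "nca_result")
}

#' Steady-state (multiple-dose) non-compartmental analysis
#'
#' For a profile sampled over one dosing interval at steady state (times
#' relative to the interval's dose). Adds the interval AUC, average and
#' trough concentrations, fluctuation `(Cmax - Cmin)/Cavg x 100`, and the
#' accumulation index `1/(1 - exp(-lambda_z * tau))` predicted from the
#' terminal slope. If sampling stops short of `tau`, the interval AUC is
#' completed by log-linear extrapolation from the last quantifiable sample.
#'
#' @param profile_day6 a [concentration_time_profile()] whose regimen
#'   carries `dosing_interval_tau`.
#' @param auc_method passed to [compute_auc()].
#' @return An object of class `nca_result`.
#' @export
nca_multiple <- function(profile_day6,
                         auc_method = c("linear_up_log_down", "linear")) {
  auc_method <- match.arg(auc_method)
  .chk(inherits(profile_day6, "conc_profile"), "invalid profile")
  tau <- profile_day6$regimen$dosing_interval_tau
  if (!is.finite(tau))
    abort_validation("regimen has no dosing_interval_tau")
  out <- nca_single(profile_day6, auc_method = auc_method)
  ser <- .nca_series(profile_day6)
  ser <- ser[ser$time_h <= tau + 1e-9, ]
  t_last <- max(ser$time_h)
  auc_tau <- compute_auc(profile_day6, t_end = min(tau, t_last),
                         method = auc_method)
  if (t_last < tau && !is.na(out$lambda_z)) {
    lzfit <- estimate_lambda_z(profile_day6)
    # complete the interval from the regression through the terminal phase
    auc_tau <- auc_tau + lzfit$clast_pred / out$lambda_z *
      (1 - exp(-out$lambda_z * (tau - t_last)))
  }
  out$auc_tau <- auc_tau
  out$cavg <- auc_tau / tau
  out$cmin <- min(ser$conc[ser$conc > 0])
  out$fluctuation_pct <- (out$cmax - out$cmin) / out$cavg * 100
  if (!is.na(out$lambda_z))
    out$accumulation_index <- 1 / (1 - exp(-out$lambda_z * tau))
  out
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA: subject %s (%s, %g mg, %s)\n", x$subject_id,
              x$cohort_id, x$dose_mg, x$occasion))
  cat(sprintf("  Cmax %.4g ng/ml at %.3g h; AUC0-t %.4g h*ng/ml\n",
              x$cmax, x$tmax, x$auc_last))
  if (!is.na(x$t_half))
    cat(sprintf("  t1/2 %.3g h; CL %.3g L/h; Vd %.3g L\n",
                x$t_half, x$cl, x$vd))
  else
    cat(sprintf("  terminal slope not estimable: %s\n", x$lambda_z_reason))
  invisible(x)
}

#' Run NCA over a list of profiles
#'
#' Dispatches each profile to [nca_single()] or [nca_multiple()] by whether
#' its regimen carries a dosing interval and the occasion is `"day6"`.
#' Profiles with no quantifiable concentration (e.g. placebo) are skipped.
#'
#' @param profiles list of [concentration_time_profile()] objects.
#' @param auc_method passed through.
#' @return A data.frame, one row per analysable profile.
#' @export
nca_table <- function(profiles,
                      auc_method = c("linear_up_log_down", "linear")) {
  auc_method <- match.arg(auc_method)
  rows <- lapply(profiles, function(p) {
    res <- tryCatch({
      if (!is.na(p$regimen$dosing_interval_tau) && p$occasion == "day6")
        nca_multiple(p, auc_method = auc_method)
      else nca_single(p, auc_method = auc_method)
    }, saapk_validation_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    as.data.frame(unclass(res), stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
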