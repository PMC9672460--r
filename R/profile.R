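#' A single subject's concentration-time profile
#'
#' The unit of exchange between the simulator, the synthetic-trial
#' generator and the NCA/dose-proportionality stages. Concentrations below
#' the assay's lower limit of quantification are carried as a flag, never
#' as a number.
#'
#' @param subject_id,cohort_id identifiers.
#' @param dose_mg dose per administration, mg.
#' @param regimen a [dose_regimen()].
#' @param occasion `"single"`, `"day1"` or `"day6"`.
#' @param time_h strictly increasing sampling times, h (for multiple-dose
#'   occasions, time since first dose).
#' @param conc_ng_ml concentrations, ng/ml; `NA` where below the limit.
#' @param blq logical below-limit flags (default: `is.na(conc_ng_ml)`).
#' @param lloq lower limit of quantification, ng/ml.
#' @return An object of class `conc_profile`.
#' @export
concentration_time_profile <- function(subject_id, cohort_id, dose_mg,
                                       regimen, occasion, time_h,
                                       conc_ng_ml,
                                       blq = is.na(conc_ng_ml),
                                       lloq = 0) {
  .chk(inherits(regimen, "dose_regimen"), "regimen must be a dose_regimen")
  .chk(occasion %in% c("single", "day1", "day6"), "invalid occasion")
  .chk(length(time_h) == length(conc_ng_ml) &&
         length(blq) == length(time_h), "sample vectors length mismatch")
  .chk(all(time_h >= 0), "sample times must be >= 0")
  .chk(all(diff(time_h) > 0),
       sprintf("sample times must be strictly increasing (subject %s)",
               subject_id))
  .chk(all(is.na(conc_ng_ml[blq])),
       "below-limit samples must carry NA concentrations")
  .chk(all(conc_ng_ml[!blq] >= 0), "concentrations must be >= 0")
  structure(list(subject_id = as.character(subject_id),
                 cohort_id = as.character(cohort_id),
                 dose_mg = dose_mg, regimen = regimen, occasion = occasion,
                 samples = data.frame(time_h = time_h,
                                      conc_ng_ml = conc_ng_ml, blq = blq),
                 lloq = lloq),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  nq <- sum(!x$samples$blq)
  cat(sprintf(
    "Profile %s (%s, %g mg, %s): %d samples (%d quantifiable), LLOQ %g\n",
    x$subject_id, x$cohort_id, x$dose_mg, x$occasion,
    nrow(x$samples), nq, x$lloq))
  invisible(x)
}

# quantifiable samples as a data.frame(time_h, conc)
.quantifiable <- function(profile) {
  s <- profile$samples[!profile$samples$blq, c("time_h", "conc_ng_ml")]
  names(s) <- c("time_h", "conc")
  s
}
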