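# Shared readers/writers. All tabular interchange is delimited text with
# an explicit header; configs are JSON. Writes are atomic
# (temp-then-rename) so partial outputs never masquerade as complete.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not move temporary file onto %s", path))
  invisible(path)
}

.CONC_COLUMNS <- c("subject_id", "cohort", "dose_mg", "time_h",
                   "conc_ng_ml", "lloq_ng_ml")

#' Write concentration-time profiles as a tidy delimited table
#'
#' Columns: `subject_id, cohort, dose_mg, time_h, conc_ng_ml, lloq_ng_ml,
#' occasion, infusion_h, tau_h, n_doses, treatment`. Below-limit samples
#' are written as the token `BLQ`.
#'
#' @param profiles list of [concentration_time_profile()] objects.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, cohort = p$cohort_id,
               dose_mg = p$dose_mg, time_h = p$samples$time_h,
               conc_ng_ml = ifelse(p$samples$blq, "BLQ",
                                   as.character(p$samples$conc_ng_ml)),
               lloq_ng_ml = p$lloq, occasion = p$occasion,
               infusion_h = p$regimen$infusion_duration,
               tau_h = p$regimen$dosing_interval_tau,
               n_doses = p$regimen$n_doses,
               treatment = if (is.null(p$treatment)) "active"
                 else p$treatment,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  atomic_write(path, function(tmp)
    write.csv(tab, tmp, row.names = FALSE, quote = FALSE))
}

#' Read a tidy concentration table into profiles
#'
#' Inverse of [write_concentration_table()]. The token `BLQ` (or an empty
#' cell) marks a below-limit sample. Rows are grouped by subject, occasion
#' and cohort; times must be strictly increasing within each group.
#'
#' @param path CSV path.
#' @return List of [concentration_time_profile()] objects.
#' @export
read_concentration_table <- function(path) {
  .chk(file.exists(path), sprintf("file not found: %s", path))
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(conc_ng_ml = "character"))
  miss <- setdiff(.CONC_COLUMNS, names(tab))
  if (length(miss))
    abort_validation(sprintf("concentration table missing column(s): %s",
                             paste(miss, collapse = ", ")))
  if (!"occasion" %in% names(tab)) tab$occasion <- "single"
  if (!"infusion_h" %in% names(tab)) tab$infusion_h <- 1
  if (!"tau_h" %in% names(tab)) tab$tau_h <- NA_real_
  if (!"n_doses" %in% names(tab)) tab$n_doses <- 1L
  if (!"treatment" %in% names(tab)) tab$treatment <- "active"

  key <- interaction(tab$subject_id, tab$occasion, drop = TRUE)
  lapply(split(tab, key), function(g) {
    if (any(diff(g$time_h) <= 0))
      abort_validation(sprintf(
        "non-increasing sample times for subject %s (%s)",
        g$subject_id[1], g$occasion[1]))
    blq <- g$conc_ng_ml %in% c("BLQ", "blq", "") | is.na(g$conc_ng_ml)
    conc <- suppressWarnings(as.numeric(g$conc_ng_ml))
    if (any(!blq & is.na(conc)))
      abort_validation(sprintf(
        "non-numeric concentration for subject %s: '%s'",
        g$subject_id[1], g$conc_ng_ml[!blq & is.na(conc)][1]))
    conc[blq] <- NA_real_
    reg <- dose_regimen(g$dose_mg[1], g$infusion_h[1],
                        dosing_interval_tau = g$tau_h[1],
                        n_doses = max(1L, g$n_doses[1]))
    pr <- concentration_time_profile(
      g$subject_id[1], g$cohort[1], g$dose_mg[1], reg, g$occasion[1],
      time_h = g$time_h, conc_ng_ml = conc, blq = blq,
      lloq = g$lloq_ng_ml[1])
    if (g$treatment[1] != "active") pr$treatment <- g$treatment[1]
    pr
  })
}

#' Export a simulation as delimited text
#' @param sim a `pbpk_sim`.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  atomic_write(path, function(tmp)
    write.csv(as.data.frame(sim), tmp, row.names = FALSE))
}

#' Build a run manifest
#'
#' Records the package version, seeds, input-file digests, the
#' configuration snapshot and a timestamp — enough to re-run a pipeline
#' stage bit-identically (deterministic stages) or
#' distribution-identically (stochastic stages).
#'
#' @param seeds named or unnamed integer vector.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param config configuration object snapshot (will be stored as-is).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(seeds = integer(0), inputs = character(0),
                         config = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  structure(list(
    tool_version = as.character(utils::packageVersion("saapk")),
    seeds = as.list(seeds), input_digests = digests,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a manifest alongside an output
#' @param manifest a [run_manifest()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  atomic_write(path, function(tmp)
    jsonlite::write_json(unclass(manifest), tmp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null"))
}

#' Run the default analysis pipeline
#'
#' Executes stages in dependency order — synthetic-trial generation, NCA,
#' dose-proportionality — writing each stage's output and a manifest into
#' `out_dir`. Any stage error aborts downstream stages with stage context.
#'
#' @param config list with optional elements `seed` (default 1), `params`
#'   (a `pbpk_parameter_set`; default [default_human_params()]),
#'   `residual_cv`, `theta_low`, `theta_high`, `ci_level`,
#'   `min_dose` (doses below are excluded from proportionality; default
#'   20).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `profiles`, `nca`, `doseprop`,
#'   `manifest`.
#' @export
pipeline_run <- function(config = list(), out_dir = tempfile("saapk_run_")) {
  defaults <- list(seed = 1L, residual_cv = 0.10, theta_low = 0.8,
                   theta_high = 1.25, ci_level = 0.90, min_dose = 20)
  unknown <- setdiff(names(config), c(names(defaults), "params"))
  if (length(unknown))
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  params <- if (is.null(cfg$params)) default_human_params() else cfg$params
  .chk(inherits(params, "pbpk_parameter_set"), "config$params invalid")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop(sprintf(
      "pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE))
  }

  profiles <- stage("synth", generate_trial(
    default_design(), params, residual_cv = cfg$residual_cv,
    seed = cfg$seed))
  conc_path <- file.path(out_dir, "concentrations.csv")
  write_concentration_table(profiles, conc_path)

  nca <- stage("nca", nca_table(profiles))
  atomic_write(file.path(out_dir, "nca.csv"), function(tmp)
    write.csv(nca, tmp, row.names = FALSE))

  single <- nca[nca$occasion == "single" & nca$dose_mg >= cfg$min_dose, ]
  records <- rbind(
    data.frame(subject_id = single$subject_id, dose = single$dose_mg,
               parameter_name = "cmax", value = single$cmax),
    data.frame(subject_id = single$subject_id, dose = single$dose_mg,
               parameter_name = "auc_last", value = single$auc_last))
  dp <- stage("doseprop", dose_proportionality(
    records, ci_level = cfg$ci_level, theta_low = cfg$theta_low,
    theta_high = cfg$theta_high))
  dp_tab <- do.call(rbind, lapply(dp, function(r)
    data.frame(parameter_name = r$parameter_name, beta = r$beta,
               ci_low = r$beta_ci[1], ci_high = r$beta_ci[2],
               range_low = r$acceptance_range[["low"]],
               range_high = r$acceptance_range[["high"]],
               verdict = r$verdict, deviation = r$deviation_direction)))
  atomic_write(file.path(out_dir, "doseprop.csv"), function(tmp)
    write.csv(dp_tab, tmp, row.names = FALSE))

  cfg_snapshot <- cfg[setdiff(names(cfg), "params")]
  manifest <- run_manifest(seeds = c(master = cfg$seed),
                           inputs = conc_path, config = cfg_snapshot)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(profiles = profiles, nca = nca, doseprop = dp,
                 manifest = manifest, out_dir = out_dir))
}
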