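#' @useDynLib saapk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef qt rnorm rlnorm runif sd quantile optim setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# The 14-tissue whole-body set. Lung is in series (receives total cardiac
# output between the venous and arterial pools); all others are perfused in
# parallel.
.tissue_names <- c(
  "lung", "heart", "brain", "adipose", "muscle", "skin", "bone", "gut",
  "spleen", "liver", "kidney", "reproductive", "rest_of_body", "red_marrow"
)

abort_validation <- function(msg, class = "saapk_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.chk <- function(ok, msg) if (!isTRUE(ok)) abort_validation(msg)

#' Compound physicochemical and binding properties
#'
#' @param name compound name.
#' @param molecular_weight molar mass, g/mol.
#' @param fraction_unbound_plasma unbound fraction in plasma, in (0, 1].
#' @param blood_to_plasma_ratio whole-blood to plasma concentration ratio.
#' @param acid_pKa acid dissociation constant (optional; needed only for
#'   tissue-composition partition calculations).
#' @param logP octanol:water log partition coefficient (optional).
#' @return An object of class `compound_properties`.
#' @export
compound_properties <- function(name, molecular_weight,
                                fraction_unbound_plasma,
                                blood_to_plasma_ratio,
                                acid_pKa = NA_real_, logP = NA_real_) {
  .chk(is.numeric(molecular_weight) && is.finite(molecular_weight) &&
         molecular_weight > 0, "molecular_weight must be > 0")
  .chk(is.numeric(fraction_unbound_plasma) &&
         fraction_unbound_plasma > 0 && fraction_unbound_plasma <= 1,
       "fraction_unbound_plasma must lie in (0, 1]")
  .chk(is.numeric(blood_to_plasma_ratio) && blood_to_plasma_ratio > 0,
       "blood_to_plasma_ratio must be > 0")
  structure(list(name = as.character(name),
                 molecular_weight = molecular_weight,
                 fraction_unbound_plasma = fraction_unbound_plasma,
                 blood_to_plasma_ratio = blood_to_plasma_ratio,
                 acid_pKa = acid_pKa, logP = logP),
            class = "compound_properties")
}

#' Permeability-limited tissue specification
#'
#' Each tissue is split into a vascular and an extravascular sub-compartment;
#' exchange between them is governed by the permeability-surface-area
#' product `pstc` acting on unbound concentrations.
#'
#' @param tissue_name one of the 14-compartment whole-body set (see
#'   [tissue_names()]).
#' @param volume total tissue volume, L.
#' @param blood_flow tissue blood flow, L/h (for lung this equals cardiac
#'   output; lung sits in series between the venous and arterial pools).
#' @param kp tissue:plasma partition coefficient (> 0).
#' @param pstc permeability-surface-area product, L/h (>= 0).
#' @param vascular_fraction fraction of `volume` occupied by the vascular
#'   sub-compartment (default 0.05).
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(tissue_name, volume, blood_flow, kp, pstc,
                        vascular_fraction = 0.05) {
  .chk(tissue_name %in% .tissue_names,
       sprintf("unknown tissue '%s'", tissue_name))
  .chk(is.finite(volume) && volume > 0, "tissue volume must be > 0")
  .chk(is.finite(blood_flow) && blood_flow >= 0, "blood_flow must be >= 0")
  .chk(is.finite(kp) && kp > 0, "kp must be > 0")
  .chk(is.finite(pstc) && pstc >= 0, "pstc must be >= 0")
  .chk(vascular_fraction > 0 && vascular_fraction < 1,
       "vascular_fraction must lie in (0, 1)")
  structure(list(tissue_name = tissue_name, volume = volume,
                 blood_flow = blood_flow, kp = kp, pstc = pstc,
                 vascular_fraction = vascular_fraction),
            class = "tissue_spec")
}

#' The 14-compartment tissue set
#' @return Character vector of tissue names, lung first.
#' @export
tissue_names <- function() .tissue_names

#' Michaelis-Menten transporter kinetics
#'
#' OATP1B1 is the hepatic basolateral uptake transporter (blood to
#' hepatocyte); P-gp is the canalicular efflux transporter (hepatocyte to
#' bile, modelled as irreversible loss).
#'
#' @param transporter_name `"OATP1B1"` or `"P-gp"`.
#' @param vmax maximal transport rate, ng/h.
#' @param km Michaelis constant, ng/ml, referred to the unbound
#'   concentration the flux acts on.
#' @param direction `"uptake"` or `"efflux"`; defaults to the canonical
#'   direction for the named transporter.
#' @return An object of class `transporter_kinetics`.
#' @export
transporter_kinetics <- function(transporter_name, vmax, km,
                                 direction = NULL) {
  .chk(transporter_name %in% c("OATP1B1", "P-gp"),
       "transporter_name must be 'OATP1B1' or 'P-gp'")
  if (is.null(direction))
    direction <- if (transporter_name == "OATP1B1") "uptake" else "efflux"
  .chk(direction %in% c("uptake", "efflux"), "invalid direction")
  if (transporter_name == "OATP1B1")
    .chk(direction == "uptake", "OATP1B1 must be an uptake transporter")
  if (transporter_name == "P-gp")
    .chk(direction == "efflux", "P-gp must be an efflux transporter")
  .chk(is.finite(vmax) && vmax >= 0, "vmax must be >= 0")
  .chk(is.numeric(km) && !is.na(km) && km > 0, "km must be > 0")
  structure(list(transporter_name = transporter_name, vmax = vmax,
                 km = km, direction = direction),
            class = "transporter_kinetics")
}

#' Dosing regimen
#'
#' @param dose_amount dose per administration, mg.
#' @param infusion_duration infusion length, h.
#' @param dosing_interval_tau interval between doses, h (`NA` for a single
#'   dose).
#' @param n_doses number of administrations (>= 1).
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose_amount, infusion_duration,
                         dosing_interval_tau = NA_real_, n_doses = 1L) {
  .chk(is.finite(dose_amount) && dose_amount > 0, "dose_amount must be > 0")
  .chk(is.finite(infusion_duration) && infusion_duration > 0,
       "infusion_duration must be > 0")
  n_doses <- as.integer(n_doses)
  .chk(n_doses >= 1L, "n_doses must be >= 1")
  if (n_doses > 1L) {
    .chk(is.finite(dosing_interval_tau) &&
           dosing_interval_tau >= infusion_duration,
         "dosing_interval_tau must be >= infusion_duration when n_doses > 1")
  }
  structure(list(dose_amount = dose_amount,
                 infusion_duration = infusion_duration,
                 dosing_interval_tau = dosing_interval_tau,
                 n_doses = n_doses),
            class = "dose_regimen")
}

#' Assemble a whole-body PBPK parameter set
#'
#' @param compound a [compound_properties()] object.
#' @param tissues list of [tissue_spec()] objects covering all 14 tissues.
#' @param transporters list of [transporter_kinetics()] objects (hepatic).
#' @param cardiac_output total cardiac output, L/h.
#' @param venous_volume,arterial_volume blood pool volumes, L.
#' @param systemic_linear_clearance residual linear clearance from venous
#'   blood, L/h (default 0; the hepatobiliary route is the primary sink).
#' @return An object of class `pbpk_parameter_set`.
#' @export
pbpk_parameter_set <- function(compound, tissues, transporters,
                               cardiac_output, venous_volume,
                               arterial_volume,
                               systemic_linear_clearance = 0) {
  .chk(inherits(compound, "compound_properties"),
       "compound must be a compound_properties object")
  .chk(all(vapply(tissues, inherits, logical(1), "tissue_spec")),
       "tissues must be a list of tissue_spec objects")
  nm <- vapply(tissues, `[[`, character(1), "tissue_name")
  .chk(!anyDuplicated(nm), "duplicate tissue names")
  .chk(setequal(nm, .tissue_names),
       sprintf("tissues must cover the 14-compartment set; missing: %s",
               paste(setdiff(.tissue_names, nm), collapse = ", ")))
  # canonical order, lung first
  tissues <- tissues[match(.tissue_names, nm)]
  .chk(all(vapply(transporters, inherits, logical(1),
                  "transporter_kinetics")),
       "transporters must be a list of transporter_kinetics objects")
  .chk(is.finite(cardiac_output) && cardiac_output > 0,
       "cardiac_output must be > 0")
  .chk(is.finite(venous_volume) && venous_volume > 0 &&
         is.finite(arterial_volume) && arterial_volume > 0,
       "blood volumes must be > 0")
  .chk(is.finite(systemic_linear_clearance) &&
         systemic_linear_clearance >= 0,
       "systemic_linear_clearance must be >= 0")
  # venous return balance: parallel tissues must sum to cardiac output
  qpar <- sum(vapply(tissues[-1], `[[`, numeric(1), "blood_flow"))
  .chk(abs(qpar - cardiac_output) <= 1e-6 * cardiac_output,
       sprintf(paste0("sum of parallel tissue blood flows (%.6g) must ",
                      "equal cardiac output (%.6g)"), qpar, cardiac_output))
  structure(list(compound = compound, tissues = tissues,
                 transporters = transporters,
                 cardiac_output = cardiac_output,
                 venous_volume = venous_volume,
                 arterial_volume = arterial_volume,
                 systemic_linear_clearance = systemic_linear_clearance),
            class = "pbpk_parameter_set")
}

#' @export
print.pbpk_parameter_set <- function(x, ...) {
  cat(sprintf("PBPK parameter set: %s (MW %.2f g/mol, fu %.3f, B:P %.2f)\n",
              x$compound$name, x$compound$molecular_weight,
              x$compound$fraction_unbound_plasma,
              x$compound$blood_to_plasma_ratio))
  cat(sprintf("  %d tissues, cardiac output %.1f L/h, blood %.2f + %.2f L\n",
              length(x$tissues), x$cardiac_output, x$venous_volume,
              x$arterial_volume))
  for (tr in x$transporters)
    cat(sprintf("  %s (%s): Vmax %.4g ng/h, Km %.4g ng/ml\n",
                tr$transporter_name, tr$direction, tr$vmax, tr$km))
  if (x$systemic_linear_clearance > 0)
    cat(sprintf("  residual systemic clearance %.3g L/h\n",
                x$systemic_linear_clearance))
  invisible(x)
}

# unbound fraction in blood under the kp-on-total convention
.fu_blood <- function(compound) {
  compound$fraction_unbound_plasma / compound$blood_to_plasma_ratio
}

.get_transporter <- function(params, name) {
  for (tr in params$transporters) if (tr$transporter_name == name) return(tr)
  NULL
}

#' Rescale or re-centre the hepatic transporter kinetics
#'
#' Multiplies every transporter's Vmax by `vmax_scale` and, when `km` is
#' given, sets the shared Michaelis constant on both transporters (the
#' shared-Km convention; independent values can still be set by editing
#' the `transporters` list directly).
#'
#' @param params a [pbpk_parameter_set()].
#' @param vmax_scale multiplier applied to all Vmax values.
#' @param km new shared km, ng/ml (`NULL` to leave unchanged).
#' @return The updated parameter set.
#' @export
set_transporter <- function(params, vmax_scale = 1, km = NULL) {
  params$transporters <- lapply(params$transporters, function(tr) {
    tr$vmax <- tr$vmax * vmax_scale
    if (!is.null(km)) tr$km <- km
    tr
  })
  params
}

#' Read a PBPK parameter set from a JSON configuration file
#'
#' The file mirrors the `pbpk_parameter_set` field names; see the packaged
#' default (`system.file("extdata", "default_params.json", package =
#' "saapk")`) for the schema.
#'
#' @param path path to a JSON file.
#' @return A `pbpk_parameter_set`.
#' @export
read_pbpk_config <- function(path) {
  .chk(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("compound", "tissues", "transporters", "cardiac_output",
           "venous_volume", "arterial_volume")
  miss <- setdiff(req, names(cfg))
  .chk(length(miss) == 0,
       sprintf("config missing keys: %s", paste(miss, collapse = ", ")))
  cp <- cfg$compound
  compound <- compound_properties(
    name = cp$name, molecular_weight = cp$molecular_weight,
    fraction_unbound_plasma = cp$fraction_unbound_plasma,
    blood_to_plasma_ratio = cp$blood_to_plasma_ratio,
    acid_pKa = if (is.null(cp$acid_pKa)) NA_real_ else cp$acid_pKa,
    logP = if (is.null(cp$logP)) NA_real_ else cp$logP)
  tis <- cfg$tissues
  tissues <- lapply(seq_len(nrow(tis)), function(i)
    tissue_spec(tis$tissue_name[i], tis$volume[i], tis$blood_flow[i],
                tis$kp[i], tis$pstc[i],
                if ("vascular_fraction" %in% names(tis))
                  tis$vascular_fraction[i] else 0.05))
  tra <- cfg$transporters
  transporters <- lapply(seq_len(nrow(tra)), function(i)
    transporter_kinetics(tra$transporter_name[i], tra$vmax[i], tra$km[i]))
  pbpk_parameter_set(
    compound = compound, tissues = tissues, transporters = transporters,
    cardiac_output = cfg$cardiac_output,
    venous_volume = cfg$venous_volume,
    arterial_volume = cfg$arterial_volume,
    systemic_linear_clearance =
      if (is.null(cfg$systemic_linear_clearance)) 0
      else cfg$systemic_linear_clearance)
}

#' Write a PBPK parameter set to a JSON configuration file
#' @param params a `pbpk_parameter_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pbpk_config <- function(params, path) {
  tis <- do.call(rbind, lapply(params$tissues, function(t)
    data.frame(tissue_name = t$tissue_name, volume = t$volume,
               blood_flow = t$blood_flow, kp = t$kp, pstc = t$pstc,
               vascular_fraction = t$vascular_fraction)))
  tra <- do.call(rbind, lapply(params$transporters, function(t)
    data.frame(transporter_name = t$transporter_name, vmax = t$vmax,
               km = t$km, direction = t$direction)))
  obj <- list(compound = params$compound[!vapply(params$compound, function(z)
                length(z) == 1 && is.na(z), logical(1))],
              tissues = tis, transporters = tra,
              cardiac_output = params$cardiac_output,
              venous_volume = params$venous_volume,
              arterial_volume = params$arterial_volume,
              systemic_linear_clearance =
                params$systemic_linear_clearance)
  atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  invisible(path)
}

#' Packaged default human PBPK parameter set
#'
#' A 70-kg adult: reference tissue volumes and blood-flow fractions of
#' cardiac output from standard physiology compilations, partition
#' coefficients from the tissue-composition method for a monoprotic acid,
#' and hepatic OATP1B1/P-gp Michaelis-Menten parameters calibrated in this
#' package against single ascending-dose exposure summaries (see the
#' methods vignette; the transporter numbers are a repository calibration,
#' not literature measurements).
#'
#' @return A `pbpk_parameter_set`.
#' @export
default_human_params <- function() {
  read_pbpk_config(system.file("extdata", "default_params.json",
                               package = "saapk", mustWork = TRUE))
}
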