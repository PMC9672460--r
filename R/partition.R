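#' Tissue composition record for partition-coefficient prediction
#'
#' @param tissue_name tissue label.
#' @param f_extracellular_water,f_intracellular_water,f_neutral_lipid,f_neutral_phospholipid
#'   volume fractions of tissue.
#' @param albumin_ratio_or_acidic_phospholipid tissue:plasma ratio of the
#'   binding protein (albumin for acids) or acidic-phospholipid content for
#'   bases; the monoprotic-acid equation implemented here uses it as the
#'   albumin ratio.
#' @param intracellular_pH intracellular water pH.
#' @return An object of class `tissue_composition`.
#' @export
tissue_composition <- function(tissue_name, f_extracellular_water,
                               f_intracellular_water, f_neutral_lipid,
                               f_neutral_phospholipid,
                               albumin_ratio_or_acidic_phospholipid,
                               intracellular_pH = 7.0) {
  fr <- c(f_extracellular_water, f_intracellular_water, f_neutral_lipid,
          f_neutral_phospholipid)
  .chk(all(is.finite(fr)) && all(fr >= 0) && all(fr <= 1),
       "composition fractions must lie in [0, 1]")
  .chk(sum(fr) <= 1 + 1e-9, "water + lipid fractions must sum to <= 1")
  .chk(albumin_ratio_or_acidic_phospholipid >= 0,
       "binding-capacity term must be >= 0")
  .chk(intracellular_pH >= 6 && intracellular_pH <= 8,
       "intracellular pH must lie in [6, 8]")
  structure(list(tissue_name = tissue_name,
                 f_extracellular_water = f_extracellular_water,
                 f_intracellular_water = f_intracellular_water,
                 f_neutral_lipid = f_neutral_lipid,
                 f_neutral_phospholipid = f_neutral_phospholipid,
                 albumin_ratio_or_acidic_phospholipid =
                   albumin_ratio_or_acidic_phospholipid,
                 intracellular_pH = intracellular_pH),
            class = "tissue_composition")
}

# neutral-lipid / neutral-phospholipid partitioning surrogate
.lipid_term <- function(P, f_nl, f_np) P * f_nl + (0.3 * P + 0.7) * f_np

# plasma neutral lipid / phospholipid fractions (standard constants)
.F_NL_PLASMA <- 0.0023
.F_NP_PLASMA <- 0.0013

#' Tissue:plasma partition coefficient by the tissue-composition method
#'
#' Implements the monoprotic-acid form of the Rodgers-Leahy-Rowland
#' tissue-composition equation for compounds whose plasma binding protein
#' is albumin: the unbound tissue:plasma-water ratio is the sum of
#' extracellular-water, ionisation-weighted intracellular-water,
#' neutral-lipid/phospholipid, and albumin-binding terms, and `kp` is that
#' ratio scaled back to total plasma by the plasma unbound fraction.
#'
#' @param compound a [compound_properties()] with `acid_pKa` and `logP`.
#' @param comp a [tissue_composition()].
#' @param plasma_pH plasma pH (default 7.4).
#' @return Tissue:plasma partition coefficient (total:total), > 0.
#' @export
kp_rodgers_rowland_acid <- function(compound, comp, plasma_pH = 7.4) {
  .chk(inherits(compound, "compound_properties"), "invalid compound")
  .chk(inherits(comp, "tissue_composition"), "invalid tissue composition")
  if (is.na(compound$acid_pKa))
    abort_validation(paste("compound has no acid_pKa; use",
                           "kp_from_distribution() or an explicit kp"))
  .chk(!is.na(compound$logP), "compound needs logP for the lipid terms")
  fu <- compound$fraction_unbound_plasma
  pKa <- compound$acid_pKa
  P <- 10^compound$logP
  # ionisation: acid, fraction ionised grows with pH above pKa
  X <- (1 + 10^(comp$intracellular_pH - pKa)) / (1 + 10^(plasma_pH - pKa))
  Y <- 1 / (1 + 10^(plasma_pH - pKa))     # neutral fraction in plasma
  lip_t <- .lipid_term(P, comp$f_neutral_lipid, comp$f_neutral_phospholipid)
  lip_p <- .lipid_term(P, .F_NL_PLASMA, .F_NP_PLASMA)
  prot <- comp$albumin_ratio_or_acidic_phospholipid *
    max(0, 1 / fu - 1 - Y * lip_p)
  kpu <- comp$f_extracellular_water + X * comp$f_intracellular_water +
    Y * lip_t + prot
  kp <- fu * kpu
  .chk(is.finite(kp) && kp > 0, "computed kp is not positive")
  kp
}

#' Tissue:plasma partition coefficient from measured distribution data
#'
#' The ratio of tissue to plasma exposure (matched AUCs, or matched
#' single-time-point concentrations) from an in-vivo tissue-distribution
#' experiment.
#'
#' @param tissue_exposure tissue exposure, h*ng/g (or ng/g).
#' @param plasma_exposure plasma exposure on the same metric, h*ng/ml (or
#'   ng/ml).
#' @param metric `"auc"` or `"single_time"`, recorded on the result.
#' @return kp, with attribute `metric`.
#' @export
kp_from_distribution <- function(tissue_exposure, plasma_exposure,
                                 metric = c("auc", "single_time")) {
  metric <- match.arg(metric)
  .chk(is.finite(tissue_exposure) && tissue_exposure > 0,
       "tissue_exposure must be > 0")
  .chk(is.finite(plasma_exposure) && plasma_exposure > 0,
       "plasma_exposure must be > 0")
  structure(tissue_exposure / plasma_exposure, metric = metric)
}

#' Packaged standard tissue-composition table
#'
#' Human tissue-composition constants (water and lipid volume fractions and
#' tissue:plasma albumin ratios) from the standard compilations used with
#' tissue-composition partition methods. Values for `red_marrow` and
#' `rest_of_body` are surrogate entries (no standard tabulation exists for
#' the lumped compartments) and are labelled as such.
#'
#' @return A data.frame with one row per tissue and a `surrogate` flag.
#' @export
tissue_composition_defaults <- function() {
  read.csv(system.file("extdata", "tissue_composition.csv",
                       package = "saapk", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Compute kp for every tissue in the packaged composition table
#' @param compound a [compound_properties()].
#' @param plasma_pH plasma pH.
#' @return Named numeric vector of partition coefficients.
#' @export
kp_table_rlr <- function(compound, plasma_pH = 7.4) {
  tc <- tissue_composition_defaults()
  kp <- vapply(seq_len(nrow(tc)), function(i) {
    comp <- tissue_composition(
      tc$tissue_name[i], tc$f_extracellular_water[i],
      tc$f_intracellular_water[i], tc$f_neutral_lipid[i],
      tc$f_neutral_phospholipid[i], tc$albumin_ratio[i],
      tc$intracellular_pH[i])
    kp_rodgers_rowland_acid(compound, comp, plasma_pH)
  }, numeric(1))
  setNames(kp, tc$tissue_name)
}
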