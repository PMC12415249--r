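# Denisovan-vs-Neanderthal differentiation.
#
# High-ranking subjects are re-scored using only the predictions that
# distinguish the two sister lineages — those derived on the Denisovan or
# Neanderthal lineage (parietal breadth, maxilloalveolar length, facial
# breadth, facial protrusion, glenoid fossa size, malar flattening) —
# optionally augmented by M2 molar crown area, a hallmark trait that is
# much larger in Denisovans. The subject's combined score is then placed
# within the leave-one-out Neanderthal score distribution.

#' Differentiation prediction subset
#'
#' @param profile A loaded profile with `lineage_origin` annotations.
#' @param include_molar Append the molar-crown-area prediction (measurement
#'   `M2_CROWN_AREA`, predicted higher in Denisovans than Neanderthals)?
#' @return The Denisovan/Neanderthal-derived predictions (6 in the packaged
#'   profile; 7 with the molar).
#' @export
differentiation_profile <- function(profile, include_molar = FALSE) {
  validate_profile(profile)
  if (all(is.na(profile$lineage_origin)) || !"lineage_origin" %in% names(profile)) {
    stop("profile lacks lineage annotations", call. = FALSE)
  }
  out <- profile[profile$lineage_origin %in% c("DEN_DERIVED", "NEA_DERIVED"), ,
                 drop = FALSE]
  if (include_molar) {
    molar <- data.frame(prediction_id = "P19_M2CA_NEA",
                        phenotype_id = "molar_crown_area",
                        measurement_id = "M2_CROWN_AREA",
                        reference_group = "NEANDERTHAL",
                        direction = 1L,
                        lineage_origin = "DEN_DERIVED",
                        measurement_class = "LINEAR",
                        stringsAsFactors = FALSE)
    out <- rbind(as.data.frame(out), molar)
  }
  rownames(out) <- NULL
  class(out) <- c("denisovan_profile", "data.frame")
  out
}

#' Molar crown area from M2 crown diameters
#'
#' Standard odontometric rectangle product: mesiodistal length x
#' buccolingual width, in mm^2. `NA` in either dimension propagates (the
#' comparison is skipped upstream, not scored as zero).
#'
#' @param mesiodistal_mm,buccolingual_mm Crown diameters (mm), positive.
#' @return Crown area (mm^2).
#' @export
molar_crown_area <- function(mesiodistal_mm, buccolingual_mm) {
  ok <- !is.na(mesiodistal_mm) & !is.na(buccolingual_mm)
  if (any(ok & (mesiodistal_mm <= 0 | buccolingual_mm <= 0))) {
    stop("crown diameters must be positive", call. = FALSE)
  }
  mesiodistal_mm * buccolingual_mm
}

#' Percentile of a subject's score within the Neanderthal distribution
#'
#' Uses the same trimmed, interpolated empirical-CDF machinery as the
#' quantile engine, scaled to a percentile.
#'
#' @param subject_combined_score Combined score of the subject.
#' @param neanderthal_combined_scores Leave-one-out combined scores of the
#'   Neanderthal reference specimens (>= 3).
#' @return Percentile in (0, 100).
#' @export
neanderthal_percentile <- function(subject_combined_score,
                                   neanderthal_combined_scores) {
  scores <- neanderthal_combined_scores[!is.na(neanderthal_combined_scores)]
  if (length(scores) < 3L) {
    stop("need at least 3 Neanderthal scores", call. = FALSE)
  }
  cdf <- build_cdf(remove_outliers(scores))
  100 * estimate_quantile(cdf, subject_combined_score)
}

#' Differentiation scoring of test subjects against Neanderthals
#'
#' Scores the given subjects and all Neanderthal reference specimens
#' (leave-one-out) on the differentiation predictions only, then places
#' each subject's combined score within the Neanderthal score
#' distribution. Only Neanderthals with at least `min_testable` testable
#' differentiation predictions enter the comparison set.
#'
#' @param subject_ids Test subjects to place.
#' @param matrix A `"measurement_matrix"` (contain `M2_CROWN_AREA` if
#'   `include_molar`; subjects without molar data are simply untestable on
#'   that prediction).
#' @param records Specimen records.
#' @param profile Full prediction profile.
#' @param include_molar Include the molar-crown-area prediction?
#' @param min_testable Minimum testable differentiation predictions for a
#'   Neanderthal to enter the comparison set (default 5).
#' @return `data.frame`: subject scores plus `neanderthal_percentile` and
#'   an `include_molar` flag column.
#' @export
differentiate_subjects <- function(subject_ids, matrix, records, profile,
                                   include_molar = FALSE, min_testable = 5L) {
  dprof <- differentiation_profile(profile, include_molar = include_molar)
  sub <- records[records$specimen_id %in% subject_ids | records$group == "NEANDERTHAL", ,
                 drop = FALSE]
  scores <- score_specimens(matrix, sub, dprof)
  nea <- scores[scores$group == "NEANDERTHAL" & scores$n_tested >= min_testable, ]
  out <- scores[scores$specimen_id %in% subject_ids, , drop = FALSE]
  out$neanderthal_percentile <- vapply(out$combined_score, function(s) {
    neanderthal_percentile(s, nea$combined_score)
  }, numeric(1))
  out$include_molar <- include_molar
  rownames(out) <- NULL
  out
}
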