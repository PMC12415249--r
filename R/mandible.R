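# Mandibular prediction validation for the two confirmed Denisovan
# mandibles (Xiahe 1 and Penghu 1).
#
# Six directional mandibular predictions over five measurements are
# checked against published comparative values. A check is CONFIRMED when
# the observed value lies on the predicted side of its comparator (a
# reference-group median or mean, stored explicitly because the sources
# mix the two), CONTRADICTED when it lies on the other side, and
# UNTESTABLE when either side is unavailable. Some comparisons come from
# published figures without printed numbers; those rows carry the reported
# qualitative relation instead of values.

#' Condylar head area approximated as an ellipse
#'
#' `pi/4 * ML * AP` from the mediolateral and anteroposterior condylar
#' dimensions, in mm^2.
#'
#' @param mediolateral_mm,anteroposterior_mm Condylar dimensions (mm),
#'   positive.
#' @return Area (mm^2).
#' @export
condylar_area_ellipse <- function(mediolateral_mm, anteroposterior_mm) {
  if (any(!is.na(mediolateral_mm) & mediolateral_mm <= 0) ||
      any(!is.na(anteroposterior_mm) & anteroposterior_mm <= 0)) {
    stop("condylar dimensions must be positive", call. = FALSE)
  }
  pi / 4 * mediolateral_mm * anteroposterior_mm
}

#' Path to the packaged mandibular-check fixture
#' @return File path.
#' @export
mandible_checks_path <- function() {
  system.file("extdata", "mandible_checks.tsv", package = "deniscan",
              mustWork = TRUE)
}

#' Evaluate the mandibular prediction checks
#'
#' @param path Fixture TSV (defaults to the packaged table of published
#'   Xiahe 1 / Penghu 1 values).
#' @return The fixture `data.frame` with an `outcome` column
#'   (`CONFIRMED` / `CONTRADICTED` / `UNTESTABLE`).
#' @export
evaluate_mandibular_checks <- function(path = mandible_checks_path()) {
  checks <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("specimen", "prediction_id", "predicted_direction",
                "observed_value", "comparator_value", "reported_relation")
  missing_cols <- setdiff(required, names(checks))
  if (length(missing_cols) > 0) {
    stop("malformed fixture, missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(checks$predicted_direction %in% c(-1L, 1L))) {
    stop("malformed fixture: predicted_direction must be +1/-1", call. = FALSE)
  }
  checks$outcome <- vapply(seq_len(nrow(checks)), function(i) {
    s <- checks$predicted_direction[i]
    obs <- checks$observed_value[i]
    cmp <- checks$comparator_value[i]
    rel <- checks$reported_relation[i]
    if (!is.na(obs) && !is.na(cmp)) {
      if (obs == cmp) return("CONTRADICTED") # on the comparator: not on the predicted side
      if (sign(obs - cmp) == s) "CONFIRMED" else "CONTRADICTED"
    } else if (!is.na(rel) && rel %in% c("GREATER", "LESS")) {
      observed_sign <- if (rel == "GREATER") 1L else -1L
      if (observed_sign == s) "CONFIRMED" else "CONTRADICTED"
    } else {
      "UNTESTABLE"
    }
  }, character(1))
  checks
}

#' Summarize mandibular validation outcomes
#'
#' Confirmed-over-testable rates, per specimen and pooled, optionally
#' pooled with extra tallies from other specimens (e.g. the Harbin
#' cranium's 16 matches of 18 testable predictions). Percentages are
#' rounded to the nearest integer.
#'
#' @param checks Output of [evaluate_mandibular_checks()].
#' @param extra_confirmed,extra_testable Extra tallies to pool in.
#' @return List with `per_specimen` (data.frame), `confirmed`, `testable`,
#'   `percent` (mandibular only), and `pooled_*` including the extras.
#' @export
validation_summary <- function(checks, extra_confirmed = 0L, extra_testable = 0L) {
  stopifnot(extra_confirmed >= 0, extra_testable >= extra_confirmed)
  testable <- checks$outcome != "UNTESTABLE"
  if (!any(testable) && extra_testable == 0) {
    stop("undefined rate: no testable predictions", call. = FALSE)
  }
  confirmed <- checks$outcome == "CONFIRMED"
  per <- do.call(rbind, lapply(split(checks, checks$specimen), function(d) {
    t <- sum(d$outcome != "UNTESTABLE")
    c <- sum(d$outcome == "CONFIRMED")
    data.frame(specimen = d$specimen[1], confirmed = c, testable = t,
               percent = if (t > 0) round(100 * c / t) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  n_c <- sum(confirmed)
  n_t <- sum(testable)
  list(per_specimen = per,
       confirmed = n_c, testable = n_t,
       percent = round(100 * n_c / n_t),
       pooled_confirmed = n_c + extra_confirmed,
       pooled_testable = n_t + extra_testable,
       pooled_percent = round(100 * (n_c + extra_confirmed) / (n_t + extra_testable)))
}
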