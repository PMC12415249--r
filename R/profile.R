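# Directional prediction profile: domain model and loader.
#
# A profile row is one signed prediction: a continuous cranial measurement,
# the reference group it is tested against (AMH or Neanderthal), the
# direction in which Denisovans are predicted to deviate (+1 = higher),
# the lineage on which the underlying regulatory change arose, and whether
# the measurement is linear (mm, mm^2) or nonlinear (angle/ratio).

REFERENCE_GROUPS <- c("AMH", "NEANDERTHAL")
LINEAGE_ORIGINS <- c("AMH_DERIVED", "NEA_DEN_ANCESTOR", "NEA_DERIVED", "DEN_DERIVED")
MEASUREMENT_CLASSES <- c("LINEAR", "NONLINEAR")
SPECIMEN_GROUPS <- c("TEST", "AMH", "NEANDERTHAL", "H_ERECTUS")

validate_profile <- function(profile) {
  required <- c("prediction_id", "phenotype_id", "measurement_id",
                "reference_group", "direction", "lineage_origin",
                "measurement_class")
  missing_cols <- setdiff(required, names(profile))
  if (length(missing_cols) > 0) {
    stop("profile is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(profile) == 0) stop("profile is empty", call. = FALSE)
  if (anyDuplicated(profile$prediction_id)) {
    stop("duplicate prediction_id in profile", call. = FALSE)
  }
  if (!all(profile$direction %in% c(-1L, 1L))) {
    stop("direction must be +1 or -1", call. = FALSE)
  }
  if (!all(profile$reference_group %in% REFERENCE_GROUPS)) {
    bad <- setdiff(unique(profile$reference_group), REFERENCE_GROUPS)
    stop("unknown reference group: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(profile$lineage_origin %in% LINEAGE_ORIGINS)) {
    stop("unknown lineage_origin", call. = FALSE)
  }
  if (!all(profile$measurement_class %in% MEASUREMENT_CLASSES)) {
    stop("unknown measurement_class", call. = FALSE)
  }
  invisible(profile)
}

#' Load a directional prediction profile
#'
#' Reads a tab-separated profile file (one prediction per row, columns
#' `prediction_id`, `phenotype_id`, `measurement_id`, `reference_group`,
#' `direction`, `lineage_origin`, `measurement_class`) and validates it.
#'
#' @param path Path to a profile TSV. Defaults to the packaged Denisovan
#'   profile: 18 predictions over 12 phenotypes, 12 tested against the AMH
#'   reference distribution and 6 against the Neanderthal one.
#' @param version Version tag attached to the returned profile.
#' @return A `data.frame` of class `"denisovan_profile"`.
#' @export
load_profile <- function(path = default_profile_path(), version = "1.0") {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  profile <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse profile file: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(profile) == 0) stop("profile file is empty: ", path, call. = FALSE)
  profile$direction <- as.integer(profile$direction)
  validate_profile(profile)
  attr(profile, "version") <- version
  class(profile) <- c("denisovan_profile", class(profile))
  profile
}

#' Path to the packaged default Denisovan profile
#' @return File path of the packaged profile TSV.
#' @export
default_profile_path <- function() {
  system.file("extdata", "denisovan_profile.tsv", package = "deniscan",
              mustWork = TRUE)
}

#' @export
print.denisovan_profile <- function(x, ...) {
  cat(sprintf("Denisovan profile v%s: %d predictions, %d phenotypes (%d vs AMH, %d vs Neanderthal)\n",
              attr(x, "version") %||% "?", nrow(x),
              length(unique(x$phenotype_id)),
              sum(x$reference_group == "AMH"),
              sum(x$reference_group == "NEANDERTHAL")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter specimen records to usable test subjects
#'
#' Keeps TEST-group records that are adult and have at least `min_testable`
#' testable predictions (profile predictions whose measurement is observed
#' for the specimen). Reference-group records pass through untouched so the
#' leave-one-out control scoring still sees them.
#'
#' @param records Specimen record `data.frame` with columns `specimen_id`,
#'   `group`, `is_adult`, `n_testable`.
#' @param min_testable Minimum testable-prediction count (default 5, i.e.
#'   subjects with fewer than five testable predictions are excluded).
#' @return Filtered records, same columns.
#' @export
select_test_subjects <- function(records, min_testable = 5L) {
  stopifnot(all(c("specimen_id", "group", "is_adult", "n_testable") %in% names(records)))
  if (any(records$n_testable < 0)) stop("n_testable must be nonnegative", call. = FALSE)
  is_test <- records$group == "TEST"
  keep <- !is_test | (records$is_adult & records$n_testable >= min_testable)
  records[keep, , drop = FALSE]
}

#' Count testable predictions per specimen
#'
#' A prediction is testable for a specimen when its measurement is present
#' in the matrix and observed (non-missing) for that specimen. Computed
#' against the supplied profile rather than trusted from input metadata.
#'
#' @param matrix A measurement matrix (see [read_measurement_matrix()]).
#' @param profile A prediction profile.
#' @return Named integer vector, one entry per specimen.
#' @export
count_testable <- function(matrix, profile) {
  meas <- intersect(profile$measurement_id, colnames(matrix$values))
  counts <- vapply(rownames(matrix$values), function(sp) {
    sum(!is.na(matrix$values[sp, profile$measurement_id[profile$measurement_id %in% meas]]))
  }, integer(1))
  counts
}
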