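# Constraint-preserving permutation null.
#
# The permutation test asks whether the profile's measurements are more
# informative about a specimen than randomly chosen measurements. Each
# permutation replaces the profile's measurements with random ones drawn
# from the pool of continuous measurements available for the specimen,
# while conserving (i) the number of testable predictions, (ii) the number
# tested against each reference group, and (iii) the linear/nonlinear
# split. Because a measurement's raw direction is an arbitrary artifact of
# its definition, all measurements are first sign-aligned to a size-proxy
# anchor (biorbital breadth, EKB): a sampled measurement inherits the
# slot's predicted direction multiplied by its anchor-correlation sign.

#' Orient measurements against a size-proxy anchor
#'
#' Assigns each measurement the sign of its Pearson correlation (pairwise
#' complete) with the anchor measurement. The anchor maps to +1; a
#' zero correlation maps to +1 with a warning. Correlations with
#' `|r|` below `near_zero` are flagged in the `"near_zero"` attribute.
#'
#' @param matrix A `"measurement_matrix"`.
#' @param anchor_measurement Anchor measurement ID (default `"EKB"`,
#'   biorbital breadth).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param near_zero Absolute-correlation threshold below which the
#'   orientation is flagged as unreliable.
#' @return Named vector of +1/-1 orientations with attributes
#'   `"correlation"` and `"near_zero"`.
#' @export
orient_measurements <- function(matrix, anchor_measurement = "EKB",
                                method = c("pearson", "spearman"),
                                near_zero = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "measurement_matrix"))
  values <- matrix$values
  if (!anchor_measurement %in% colnames(values)) {
    stop("anchor measurement not in matrix: ", anchor_measurement, call. = FALSE)
  }
  anchor <- values[, anchor_measurement]
  r <- vapply(colnames(values), function(m) {
    if (m == anchor_measurement) return(1)
    ok <- !is.na(anchor) & !is.na(values[, m])
    if (sum(ok) < 3L) {
      stop("measurement ", m, " shares fewer than 3 specimens with the anchor",
           call. = FALSE)
    }
    suppressWarnings(stats::cor(anchor[ok], values[ok, m], method = method))
  }, numeric(1))
  r[is.na(r)] <- 0
  orientation <- ifelse(r >= 0, 1, -1)
  if (any(r == 0 & names(r) != anchor_measurement)) {
    warning("zero anchor correlation for: ",
            paste(names(r)[r == 0], collapse = ", "), "; oriented +1")
  }
  attr(orientation, "correlation") <- r
  attr(orientation, "near_zero") <- names(r)[abs(r) < near_zero]
  orientation
}

#' Permutation slot specification for one specimen
#'
#' Records, for each of the specimen's testable predictions, the reference
#' group, measurement class and predicted direction — the structure every
#' permutation must conserve.
#'
#' @param comparisons Output of [evaluate_predictions()] for the specimen.
#' @return A `"permutation_slot_spec"`: data.frame of slots plus summary
#'   counts in attributes.
#' @export
permutation_slot_spec <- function(comparisons) {
  if (nrow(comparisons) == 0) stop("specimen has no testable predictions", call. = FALSE)
  slots <- comparisons[, c("prediction_id", "reference_group", "measurement_class",
                           "direction")]
  rownames(slots) <- NULL
  structure(slots,
            k_total = nrow(slots),
            k_by_reference = table(factor(slots$reference_group, REFERENCE_GROUPS)),
            k_by_class = table(factor(slots$measurement_class, MEASUREMENT_CLASSES)),
            class = c("permutation_slot_spec", class(slots)))
}

#' Sample one permuted prediction set
#'
#' Draws, for each measurement class, as many pool measurements as the
#' slot specification requires (without replacement within the
#' permutation), assigns them to the slots of that class, and gives each an
#' effective direction = slot direction x anchor orientation of the sampled
#' measurement.
#'
#' @param slot_spec A `"permutation_slot_spec"`.
#' @param measurement_pool Named list mapping `"LINEAR"` and `"NONLINEAR"`
#'   to character vectors of candidate measurement IDs.
#' @param orientation Named +1/-1 vector from [orient_measurements()].
#' @return `data.frame` with columns `prediction_id`, `reference_group`,
#'   `measurement_class`, `measurement_id`, `direction` (the effective,
#'   orientation-adjusted direction).
#' @export
sample_permuted_profile <- function(slot_spec, measurement_pool, orientation) {
  classes <- unique(slot_spec$measurement_class)
  picked <- rep(NA_character_, nrow(slot_spec))
  for (cl in classes) {
    idx <- which(slot_spec$measurement_class == cl)
    pool <- measurement_pool[[cl]]
    if (length(pool) < length(idx)) {
      stop(sprintf("measurement pool exhausted for class %s: need %d, have %d",
                   cl, length(idx), length(pool)), call. = FALSE)
    }
    picked[idx] <- pool[sample.int(length(pool), length(idx))]
  }
  data.frame(prediction_id = slot_spec$prediction_id,
             reference_group = slot_spec$reference_group,
             measurement_class = slot_spec$measurement_class,
             measurement_id = picked,
             direction = as.integer(slot_spec$direction *
                                      orientation[picked]),
             stringsAsFactors = FALSE)
}

# Precompute, for one specimen, the quantile of its value on every pool
# measurement within each reference distribution (leave-one-out if the
# specimen is a reference member). Returns a measurements x 2 matrix of
# quantiles (NA where the specimen's value is missing or the reference is
# too thin).
specimen_quantile_table <- function(specimen_id, matrix, reference_groups,
                                    measurements = colnames(matrix$values)) {
  values <- matrix$values
  q <- matrix(NA_real_, nrow = length(measurements), ncol = length(REFERENCE_GROUPS),
              dimnames = list(measurements, REFERENCE_GROUPS))
  for (m in measurements) {
    t <- values[specimen_id, m]
    if (is.na(t)) next
    for (ref in REFERENCE_GROUPS) {
      ref_ids <- setdiff(reference_groups[[ref]], specimen_id)
      ref_vals <- values[ref_ids, m]
      ref_vals <- ref_vals[!is.na(ref_vals)]
      if (length(ref_vals) < 3L) next
      cdf <- build_cdf(remove_outliers(ref_vals))
      q[m, ref] <- estimate_quantile(cdf, t)
    }
  }
  q
}

#' Permutation test for one specimen's profile match
#'
#' Compares the specimen's observed combined score to the distribution of
#' combined scores over permuted prediction sets. The raw permutation
#' p-value is the fraction of permutations whose combined score is greater
#' than or equal to the observed one (ties count toward the numerator).
#'
#' @param specimen_id Specimen to test.
#' @param profile Prediction profile.
#' @param matrix A `"measurement_matrix"`.
#' @param reference_groups Named list of reference specimen IDs (as in
#'   [evaluate_predictions()]).
#' @param n_perm Number of permutations (default 10000).
#' @param orientation Optional precomputed orientation map; computed from
#'   `anchor_measurement` otherwise.
#' @param anchor_measurement Anchor for [orient_measurements()].
#' @param pool_measurements Optional character vector restricting the
#'   sampling pool; defaults to all matrix measurements observed for the
#'   specimen. Profile measurements stay in the pool and may be redrawn.
#' @param add_one Use the (b + 1) / (N + 1) smoothed estimator instead of
#'   b / N (off by default).
#' @param binomial_method Passed to [binomial_score()].
#' @return A `"permutation_result"` list: `specimen_id`,
#'   `observed_combined`, `permuted_combined`, `p_raw`, `n_perm`.
#' @export
permutation_test <- function(specimen_id, profile, matrix, reference_groups,
                             n_perm = 10000L, orientation = NULL,
                             anchor_measurement = "EKB",
                             pool_measurements = NULL,
                             add_one = FALSE,
                             binomial_method = "midp") {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  cmp <- evaluate_predictions(specimen_id, profile, matrix, reference_groups)
  if (nrow(cmp) == 0) stop("specimen has no testable predictions: ", specimen_id,
                           call. = FALSE)
  b <- binomial_score(cmp$distance, method = binomial_method)
  w <- wilcoxon_score(cmp$distance)
  observed <- combined_score(b$score, w$score)
  spec <- permutation_slot_spec(cmp)
  if (is.null(orientation)) {
    orientation <- orient_measurements(matrix, anchor_measurement)
  }
  values <- matrix$values
  if (is.null(pool_measurements)) pool_measurements <- colnames(values)
  observed_meas <- pool_measurements[!is.na(values[specimen_id, pool_measurements])]
  # every pool measurement must have a usable quantile in the reference
  # groups the slots draw on
  qtab <- specimen_quantile_table(specimen_id, matrix, reference_groups,
                                  observed_meas)
  refs_needed <- names(which(attr(spec, "k_by_reference") > 0))
  usable <- observed_meas[apply(!is.na(qtab[observed_meas, refs_needed, drop = FALSE]),
                                1, all)]
  pool <- split(usable, matrix$classes[usable])
  for (cl in names(which(attr(spec, "k_by_class") > 0))) {
    if (length(pool[[cl]] %||% character(0)) < attr(spec, "k_by_class")[[cl]]) {
      stop("measurement pool exhausted for class ", cl, call. = FALSE)
    }
  }
  slot_ref <- spec$reference_group
  permuted <- vapply(seq_len(n_perm), function(i) {
    perm <- sample_permuted_profile(spec, pool, orientation)
    q <- qtab[cbind(perm$measurement_id, slot_ref)]
    d <- 2 * perm$direction * (q - 0.5)
    pb <- binomial_score(d, method = binomial_method)
    pw <- wilcoxon_score(d)
    combined_score(pb$score, pw$score)
  }, numeric(1))
  p_raw <- if (add_one) (sum(permuted >= observed) + 1) / (n_perm + 1)
           else sum(permuted >= observed) / n_perm
  structure(list(specimen_id = specimen_id,
                 observed_combined = observed,
                 permuted_combined = permuted,
                 p_raw = p_raw,
                 n_perm = as.integer(n_perm)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test %s: S_obs = %.3f, p_raw = %.4g (N = %d)\n",
              x$specimen_id, x$observed_combined, x$p_raw, x$n_perm))
  invisible(x)
}

#' Permutation tests for a batch of test subjects with BH adjustment
#'
#' Runs [permutation_test()] for each test subject and BH-adjusts the raw
#' p-values across the family of test subjects with at least
#' `min_testable` testable predictions (subjects below the threshold are
#' reported with `p_adjusted = NA`).
#'
#' @param matrix A `"measurement_matrix"`.
#' @param records Specimen records.
#' @param profile Prediction profile.
#' @param n_perm Permutations per subject.
#' @param min_testable BH family threshold (default 5).
#' @param ... Passed to [permutation_test()].
#' @return `data.frame`: `specimen_id`, `n_tested`, `observed_combined`,
#'   `p_raw`, `p_adjusted`, `n_perm`.
#' @export
run_permutation_tests <- function(matrix, records, profile, n_perm = 10000L,
                                  min_testable = 5L,
                                  anchor_measurement = "EKB", ...) {
  reference_groups <- split(records$specimen_id, records$group)
  reference_groups <- reference_groups[intersect(REFERENCE_GROUPS, names(reference_groups))]
  subjects <- records$specimen_id[records$group == "TEST"]
  orientation <- orient_measurements(matrix, anchor_measurement)
  rows <- lapply(subjects, function(sp) {
    res <- permutation_test(sp, profile, matrix, reference_groups,
                            n_perm = n_perm, orientation = orientation, ...)
    k <- attr(permutation_slot_spec(
      evaluate_predictions(sp, profile, matrix, reference_groups)), "k_total")
    data.frame(specimen_id = sp, n_tested = k,
               observed_combined = res$observed_combined,
               p_raw = res$p_raw, n_perm = res$n_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  fam <- out$n_tested >= min_testable
  if (any(fam)) {
    # a permutation p of exactly 0 means "below the resolution of N
    # permutations"; floor at the add-one estimate 1/(N + 1) before BH,
    # which requires values in (0, 1]
    p <- pmax(out$p_raw[fam], 1 / (out$n_perm[fam] + 1))
    out$p_adjusted[fam] <- bh_adjust(p)
  }
  rownames(out) <- NULL
  out[, c("specimen_id", "n_tested", "observed_combined", "p_raw",
          "p_adjusted", "n_perm")]
}
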