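# Per-specimen scoring of agreement with the directional profile.
#
# Each testable prediction contributes a signed phenotypic distance
# d = 2s(q - 1/2). Two scores summarize the d's: a one-sided binomial
# mid-p on the count of positive distances (match = strictly positive),
# and a one-sided Wilcoxon signed-rank on their median. Scores are
# S = -log10(P); the combined statistic is the Euclidean norm
# sqrt(S_binom^2 + S_wilcoxon^2). Because the underlying measurements are
# correlated, these p-values are treated as similarity scores, not as
# calibrated significance — calibration comes from the permutation null.

P_FLOOR <- 1e-300

#' Evaluate a specimen's measurements against a prediction profile
#'
#' For every profile prediction whose measurement is observed for the
#' specimen, estimates the quantile of the specimen's value within the
#' prediction's reference-group distribution (Tukey-trimmed, interpolated
#' CDF) and converts it to a signed phenotypic distance. When the specimen
#' itself belongs to the reference group it is excluded from that group's
#' distribution (leave-one-out control scoring).
#'
#' @param specimen_id Specimen to evaluate.
#' @param profile Prediction profile (see [load_profile()]).
#' @param matrix A `"measurement_matrix"` holding the specimen and the
#'   reference individuals.
#' @param reference_groups Named list mapping `"AMH"` and `"NEANDERTHAL"`
#'   to character vectors of reference specimen IDs.
#' @return A `data.frame` with one row per testable prediction
#'   (`prediction_id`, `measurement_id`, `reference_group`, `direction`,
#'   `measurement_class`, `observed`, `quantile`, `distance`). Zero rows
#'   (with attribute `empty = TRUE`) when nothing is testable.
#' @export
evaluate_predictions <- function(specimen_id, profile, matrix, reference_groups) {
  stopifnot(inherits(matrix, "measurement_matrix"))
  validate_profile(profile)
  values <- matrix$values
  if (!specimen_id %in% rownames(values)) {
    stop("specimen not in matrix: ", specimen_id, call. = FALSE)
  }
  groups <- names(reference_groups)
  if (!all(unique(profile$reference_group) %in% groups)) {
    stop("reference_groups must cover every group the profile tests against",
         call. = FALSE)
  }
  rows <- vector("list", nrow(profile))
  for (i in seq_len(nrow(profile))) {
    m <- profile$measurement_id[i]
    if (!m %in% colnames(values)) next
    t <- values[specimen_id, m]
    if (is.na(t)) next
    ref <- profile$reference_group[i]
    ref_ids <- setdiff(reference_groups[[ref]], specimen_id)
    ref_vals <- values[ref_ids, m]
    ref_vals <- ref_vals[!is.na(ref_vals)]
    if (length(ref_vals) < 3L) {
      stop(sprintf("insufficient %s reference values for measurement %s", ref, m),
           call. = FALSE)
    }
    cdf <- build_cdf(remove_outliers(ref_vals))
    q <- estimate_quantile(cdf, t)
    rows[[i]] <- data.frame(
      prediction_id = profile$prediction_id[i],
      measurement_id = m,
      reference_group = ref,
      direction = profile$direction[i],
      measurement_class = profile$measurement_class[i],
      observed = t,
      quantile = q,
      distance = phenotypic_distance(q, profile$direction[i]),
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(prediction_id = character(0), measurement_id = character(0),
                      reference_group = character(0), direction = integer(0),
                      measurement_class = character(0), observed = numeric(0),
                      quantile = numeric(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "empty") <- FALSE
  out
}

#' One-sided binomial score on the count of positive distances
#'
#' Tests whether the number of strictly positive phenotypic distances
#' exceeds the Binomial(k, 1/2) expectation. The default `"midp"` method is
#' the mid-p correction: `P = P(X > n_pos) + 0.5 * P(X = n_pos)`. A zero
#' distance counts as a non-match. `"exact"` (plain upper tail including
#' the observed count) and `"normal"` (continuity-corrected normal
#' approximation) are available for comparison.
#'
#' @param distances Numeric vector of phenotypic distances (k >= 1).
#' @param method `"midp"` (default), `"exact"`, or `"normal"`.
#' @return List with `n_tested`, `n_positive`, `p`, `score` (= -log10 p).
#' @export
binomial_score <- function(distances, method = c("midp", "exact", "normal")) {
  method <- match.arg(method)
  distances <- distances[!is.na(distances)]
  k <- length(distances)
  if (k == 0) stop("binomial score undefined for zero distances", call. = FALSE)
  n_pos <- sum(distances > 0)
  p <- switch(method,
    midp = stats::pbinom(n_pos, k, 0.5, lower.tail = FALSE) +
      0.5 * stats::dbinom(n_pos, k, 0.5),
    exact = stats::pbinom(n_pos - 1, k, 0.5, lower.tail = FALSE),
    normal = stats::pnorm((n_pos - 0.5 - k / 2) / sqrt(k / 4), lower.tail = FALSE)
  )
  p <- min(max(p, P_FLOOR), 1)
  list(n_tested = k, n_positive = n_pos, p = p, score = -log10(p))
}

#' One-sided Wilcoxon signed-rank score on the distances
#'
#' Tests whether the median phenotypic distance exceeds zero. Asymptotic
#' normal approximation with mean ranks for tied absolute distances and
#' Pratt handling of zeros (zeros are ranked, then dropped from the
#' statistic), with a tie-corrected variance. An exact sign-flip
#' enumeration is available for small k via [wilcoxon_exact_p()].
#'
#' @param distances Numeric vector of phenotypic distances (k >= 1).
#' @return List with `statistic` (sum of positive ranks), `p`, `score`
#'   (= -log10 p), `degenerate` (TRUE when every distance is zero, in which
#'   case p = 0.5 by convention).
#' @export
wilcoxon_score <- function(distances) {
  d <- distances[!is.na(distances)]
  if (length(d) == 0) stop("wilcoxon score undefined for zero distances", call. = FALSE)
  n <- length(d)
  if (all(d == 0)) {
    return(list(statistic = 0, p = 0.5, score = -log10(0.5), degenerate = TRUE))
  }
  r <- rank(abs(d), ties.method = "average")
  n0 <- sum(d == 0)
  w <- sum(r[d > 0])
  e_w <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  # tie correction over groups of tied nonzero |d|
  nonzero_r <- r[d != 0]
  tie_sizes <- table(nonzero_r)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / 48
  v_w <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 - tie_term
  if (v_w <= 0) {
    return(list(statistic = w, p = 0.5, score = -log10(0.5), degenerate = TRUE))
  }
  z <- (w - e_w) / sqrt(v_w)
  p <- stats::pnorm(z, lower.tail = FALSE)
  p <- min(max(p, P_FLOOR), 1)
  list(statistic = w, p = p, score = -log10(p), degenerate = FALSE)
}

#' Exact one-sided signed-rank p by sign-flip enumeration
#'
#' Enumerates all 2^k sign assignments of the absolute distances (zeros
#' kept, Pratt-style: ranked but contributing no sign) and returns the
#' fraction of assignments whose positive-rank sum is at least the observed
#' one. Exact cross-check for the asymptotic [wilcoxon_score()]; intended
#' for k <= 12.
#'
#' @param distances Numeric vector (k >= 1, k <= 20 enforced).
#' @return Exact p-value.
#' @export
wilcoxon_exact_p <- function(distances) {
  d <- distances[!is.na(distances)]
  k <- length(d)
  if (k == 0) stop("undefined for zero distances", call. = FALSE)
  if (k > 20) stop("exact enumeration limited to k <= 20", call. = FALSE)
  r <- rank(abs(d), ties.method = "average")
  nonzero <- d != 0
  w_obs <- sum(r[d > 0])
  rk <- r[nonzero]
  m <- length(rk)
  if (m == 0) return(1)
  # all sign assignments of the nonzero ranks
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% rk)
  mean(w_all >= w_obs - 1e-12)
}

#' Combined profile-match statistic
#'
#' Euclidean combination `sqrt(s_b^2 + s_w^2)` of the binomial and Wilcoxon
#' scores.
#'
#' @param s_b,s_w Nonnegative scores.
#' @return Combined score.
#' @export
combined_score <- function(s_b, s_w) {
  if (any(s_b < 0) || any(s_w < 0)) stop("scores must be nonnegative", call. = FALSE)
  sqrt(s_b^2 + s_w^2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; order preserved, each adjusted
#' value >= its raw p and capped at 1. Applied across test subjects only —
#' reference specimens' control scores are reported unadjusted.
#'
#' @param p_values Numeric vector in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Score every specimen against the profile
#'
#' Computes the full score table: test subjects scored against the
#' reference distributions, and each reference specimen scored leave-one-out
#' against its own group as a control.
#'
#' @param matrix A `"measurement_matrix"`.
#' @param records Specimen records (`specimen_id`, `group`, `is_adult`,
#'   `n_testable`).
#' @param profile Prediction profile.
#' @param binomial_method Passed to [binomial_score()].
#' @return A `data.frame` with one row per scoreable specimen:
#'   `specimen_id`, `group`, `n_tested`, `n_positive`, `binomial_p`,
#'   `binomial_score`, `wilcoxon_p`, `wilcoxon_score`, `combined_score`.
#' @export
score_specimens <- function(matrix, records, profile, binomial_method = "midp") {
  reference_groups <- split(records$specimen_id, records$group)
  reference_groups <- reference_groups[intersect(REFERENCE_GROUPS, names(reference_groups))]
  rows <- lapply(records$specimen_id, function(sp) {
    cmp <- evaluate_predictions(sp, profile, matrix, reference_groups)
    if (nrow(cmp) == 0) return(NULL)
    b <- binomial_score(cmp$distance, method = binomial_method)
    w <- wilcoxon_score(cmp$distance)
    data.frame(specimen_id = sp,
               group = records$group[records$specimen_id == sp],
               n_tested = b$n_tested, n_positive = b$n_positive,
               binomial_p = b$p, binomial_score = b$score,
               wilcoxon_p = w$p, wilcoxon_score = w$score,
               combined_score = combined_score(b$score, w$score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
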