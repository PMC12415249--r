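#' Remove Tukey-fence outliers from a reference sample
#'
#' Values below `Q1 - 1.5 * IQR` or above `Q3 + 1.5 * IQR` are discarded
#' before a reference distribution is built. Quartiles are computed by linear
#' interpolation of order statistics at positions `1 + (N - 1) * p`
#' (`stats::quantile()` type 7). Outlier trimming is applied to reference
#' groups only; a test subject's own value is never trimmed.
#'
#' @param values Numeric vector; `NA`s are dropped first.
#' @return Numeric vector of the values inside the fences, in input order.
#' @export
remove_outliers <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    stop("insufficient reference sample: need at least 3 non-missing values, got ",
         length(values), call. = FALSE)
  }
  if (!all(is.finite(values))) stop("reference values must be finite", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  values[values >= lo & values <= hi]
}

#' Build an interpolated empirical CDF from reference values
#'
#' The i-th order statistic is taken as the estimator of the
#' `(i - 0.5) / N` quantile; tied values share the mean of their quantiles;
#' quantiles between support points are linearly interpolated. Queries
#' outside the support clamp to `[0.5/N, 1 - 0.5/N]`, keeping every
#' phenotypic distance strictly inside (-1, 1).
#'
#' Callers are expected to compose with [remove_outliers()]; this function
#' uses the values it is given.
#'
#' @param reference_values Numeric vector of at least 1 finite value
#'   (reference distributions in practice come from [remove_outliers()],
#'   which enforces >= 3).
#' @return An object of class `"empirical_cdf"` with elements `support`
#'   (strictly increasing), `quantile_at_support`, `n` (the N before tie
#'   collapsing), `bounds` (`c(0.5/N, 1 - 0.5/N)`) and `degenerate` (TRUE
#'   when all reference values are identical).
#' @export
build_cdf <- function(reference_values) {
  values <- reference_values[!is.na(reference_values)]
  if (length(values) < 1L || !all(is.finite(values))) {
    stop("reference values must be finite and non-empty", call. = FALSE)
  }
  n <- length(values)
  sorted <- sort(values)
  q <- (seq_len(n) - 0.5) / n
  # ties = mean: collapse equal support values onto one point carrying the
  # mean of their plotting-position quantiles
  q_tied <- stats::ave(q, match(sorted, sorted), FUN = mean)
  keep <- !duplicated(sorted)
  support <- sorted[keep]
  quantile_at_support <- q_tied[keep]
  structure(
    list(
      support = support,
      quantile_at_support = quantile_at_support,
      n = n,
      bounds = c(0.5 / n, 1 - 0.5 / n),
      degenerate = length(support) == 1L
    ),
    class = "empirical_cdf"
  )
}

#' @export
print.empirical_cdf <- function(x, ...) {
  cat(sprintf("Empirical CDF: N = %d, support [%g, %g]%s\n",
              x$n, min(x$support), max(x$support),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Estimate the quantile of a value under an empirical CDF
#'
#' Linear interpolation between support-point quantiles; outside the support
#' the quantile clamps to the CDF's bounds. For a degenerate reference (all
#' values identical) a query equal to the single support point returns 0.5
#' and anything else returns the nearest clamp bound.
#'
#' @param cdf An `"empirical_cdf"` from [build_cdf()].
#' @param t Numeric vector of query values; `NA` propagates.
#' @return Quantiles in `[0.5/N, 1 - 0.5/N]`.
#' @export
estimate_quantile <- function(cdf, t) {
  stopifnot(inherits(cdf, "empirical_cdf"))
  out <- rep(NA_real_, length(t))
  ok <- !is.na(t)
  if (!any(ok)) return(out)
  if (any(!is.finite(t[ok]))) stop("query values must be finite or NA", call. = FALSE)
  if (cdf$degenerate) {
    v <- cdf$support
    out[ok] <- ifelse(t[ok] == v, 0.5,
                      ifelse(t[ok] < v, cdf$bounds[1], cdf$bounds[2]))
    return(out)
  }
  # rule = 2 extends the end quantiles, i.e. clamps to [0.5/N, 1 - 0.5/N]
  out[ok] <- stats::approx(cdf$support, cdf$quantile_at_support,
                           xout = t[ok], rule = 2, ties = "ordered")$y
  out
}

#' Signed phenotypic distance from a quantile
#'
#' `D = 2 * s * (q - 1/2)`, where `s` is +1 when the trait is predicted
#' higher in Denisovans than in the reference group and -1 otherwise.
#' Positive distances indicate agreement with the Denisovan prediction;
#' the distance lies strictly inside (-1, 1) because quantiles are clamped
#' away from 0 and 1.
#'
#' @param q Quantile(s) in (0, 1); `NA` propagates.
#' @param s Predicted direction, +1 or -1 (scalar or vector recycled
#'   against `q`).
#' @return Numeric distance(s) in (-1, 1).
#' @export
phenotypic_distance <- function(q, s) {
  if (!all(s %in% c(-1, 1))) stop("direction s must be +1 or -1", call. = FALSE)
  ok <- !is.na(q)
  if (any(q[ok] <= 0 | q[ok] >= 1)) {
    stop("quantiles must lie strictly inside (0, 1)", call. = FALSE)
  }
  2 * s * (q - 0.5)
}
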