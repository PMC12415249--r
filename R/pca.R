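# PCA morphospace: missingness filtering, iterative-PCA imputation,
# reference-group PCA fit, and projection of test subjects.

#' Filter a matrix by missingness
#'
#' Drops measurements with strictly more than `measurement_max_missing`
#' missing values, and specimens with strictly more than
#' `specimen_max_missing`, in the requested order. The main analysis
#' filters measurements first; filtering specimens first retains more
#' measurements at the cost of specimens.
#'
#' @param matrix A `"measurement_matrix"`.
#' @param measurement_max_missing Fraction in `[0, 1]` (default 0.20; the
#'   nonlinear-only morphospace uses 0.30).
#' @param specimen_max_missing Fraction in `[0, 1]` (default 0.15).
#' @param order `"MEASUREMENTS_FIRST"` (default) or `"SPECIMENS_FIRST"`.
#' @param classes Optional restriction to one measurement class
#'   (`"LINEAR"`/`"NONLINEAR"`) applied before filtering.
#' @return The filtered `"measurement_matrix"`.
#' @export
filter_missingness <- function(matrix, measurement_max_missing = 0.20,
                               specimen_max_missing = 0.15,
                               order = c("MEASUREMENTS_FIRST", "SPECIMENS_FIRST"),
                               classes = NULL) {
  order <- match.arg(order)
  stopifnot(measurement_max_missing >= 0, measurement_max_missing <= 1,
            specimen_max_missing >= 0, specimen_max_missing <= 1)
  values <- matrix$values
  if (!is.null(classes)) {
    keep <- names(matrix$classes)[matrix$classes %in% classes]
    values <- values[, keep, drop = FALSE]
  }
  drop_meas <- function(v) v[, colMeans(is.na(v)) <= measurement_max_missing, drop = FALSE]
  drop_spec <- function(v) v[rowMeans(is.na(v)) <= specimen_max_missing, , drop = FALSE]
  values <- if (order == "MEASUREMENTS_FIRST") drop_spec(drop_meas(values))
            else drop_meas(drop_spec(values))
  if (nrow(values) == 0 || ncol(values) == 0) {
    stop("missingness filtering left an empty matrix", call. = FALSE)
  }
  new_measurement_matrix(values, matrix$classes[colnames(values)],
                         matrix$capacity)
}

#' Impute missing cells by iterative PCA (EM-PCA)
#'
#' Initializes missing cells with column means, then alternates
#' center/scale, rank-`n_components` SVD truncation, and refilling of the
#' missing cells until the imputed values change by less than `tol`
#' (relative mean squared change) or `max_iter` is reached. Observed cells
#' are never altered.
#'
#' @param matrix A `"measurement_matrix"` (or plain numeric matrix); every
#'   row and column must have at least one observed value.
#' @param n_components Rank of the reconstruction (default 2).
#' @param scale Divide by column standard deviation (default TRUE).
#' @param tol Convergence tolerance on the relative mean-squared change of
#'   the imputed values between iterations (default 1e-14; iteration error
#'   decays linearly, so the final imputed values are accurate well beyond
#'   the square root of this).
#' @param max_iter Iteration cap (default 2000); non-convergence warns and
#'   returns the best iterate.
#' @return Completed matrix of the same type, with attributes
#'   `"iterations"` and `"converged"` on the value matrix.
#' @export
impute_iterative_pca <- function(matrix, n_components = 2L, scale = TRUE,
                                 tol = 1e-14, max_iter = 2000L) {
  is_mm <- inherits(matrix, "measurement_matrix")
  x <- if (is_mm) matrix$values else matrix
  stopifnot(is.matrix(x), is.numeric(x))
  miss <- is.na(x)
  if (!any(miss)) {
    out <- x
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    if (is_mm) { matrix$values <- out; return(matrix) }
    return(out)
  }
  if (any(rowSums(!miss) == 0)) stop("row with all cells missing", call. = FALSE)
  if (any(colSums(!miss) == 0)) stop("column with all cells missing", call. = FALSE)
  ncp <- min(n_components, nrow(x) - 1L, ncol(x))
  filled <- x
  col_means <- colMeans(x, na.rm = TRUE)
  filled[miss] <- col_means[col(x)[miss]]
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    m <- colMeans(filled)
    s <- if (scale) sqrt(colMeans(sweep(filled, 2, m)^2)) else rep(1, ncol(x))
    s[s < .Machine$double.eps] <- 1
    z <- sweep(sweep(filled, 2, m), 2, s, "/")
    sv <- svd(z, nu = ncp, nv = ncp)
    recon <- sv$u %*% (diag(sv$d[seq_len(ncp)], ncp, ncp)) %*% t(sv$v)
    xhat <- sweep(sweep(recon, 2, s, "*"), 2, m, "+")
    new_vals <- xhat[miss]
    delta <- sum((new_vals - filled[miss])^2) /
      max(sum(filled[miss]^2), .Machine$double.eps)
    filled[miss] <- new_vals
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning(sprintf("iterative PCA imputation did not converge in %d iterations (last relative change %.3g); returning best iterate",
                    max_iter, delta))
  }
  attr(filled, "iterations") <- iter
  attr(filled, "converged") <- converged
  if (is_mm) { matrix$values <- filled; return(matrix) }
  filled
}

#' Fit a PCA model on reference individuals
#'
#' Centering, scaling (population SD) and loadings are estimated from the
#' reference rows only; test subjects are later projected onto this plane.
#' Loading signs follow the convention that each component's
#' largest-magnitude element is positive.
#'
#' @param matrix Imputed (complete) `"measurement_matrix"` or numeric
#'   matrix.
#' @param reference_ids Specimen IDs to fit on (must outnumber the
#'   components).
#' @param n_components Number of components (default 2).
#' @param scale Scale columns by reference-set SD (default TRUE).
#' @return A `"cranio_pca"` model: `center`, `scale`, `loadings`
#'   (measurements x components, orthonormal), `explained_variance`.
#' @export
fit_reference_pca <- function(matrix, reference_ids, n_components = 2L,
                              scale = TRUE) {
  x <- if (inherits(matrix, "measurement_matrix")) matrix$values else matrix
  if (length(reference_ids) == 0) stop("reference_ids is empty", call. = FALSE)
  missing_ids <- setdiff(reference_ids, rownames(x))
  if (length(missing_ids) > 0) {
    stop("reference specimens not in matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(x))) stop("matrix must be imputed (complete) before PCA", call. = FALSE)
  ref <- x[reference_ids, , drop = FALSE]
  if (nrow(ref) <= n_components) {
    stop("need more reference rows than components", call. = FALSE)
  }
  center <- colMeans(ref)
  scl <- if (scale) sqrt(colMeans(sweep(ref, 2, center)^2)) else rep(1, ncol(ref))
  if (any(scl < .Machine$double.eps)) {
    stop("zero-variance measurement in reference set: ",
         paste(colnames(ref)[scl < .Machine$double.eps], collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(sweep(ref, 2, center), 2, scl, "/")
  sv <- svd(z)
  ncp <- min(n_components, length(sv$d))
  loadings <- sv$v[, seq_len(ncp), drop = FALSE]
  # deterministic sign: largest-magnitude element of each loading positive
  for (j in seq_len(ncp)) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(ref), paste0("PC", seq_len(ncp)))
  structure(list(center = center, scale = scl, loadings = loadings,
                 explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(ncp)]),
            class = "cranio_pca")
}

#' @export
print.cranio_pca <- function(x, ...) {
  cat(sprintf("Reference PCA: %d measurements, %d components (%s%% variance)\n",
              nrow(x$loadings), ncol(x$loadings),
              paste(sprintf("%.1f", 100 * x$explained_variance), collapse = "/")))
  invisible(x)
}

#' Project specimens onto a fitted PCA plane
#'
#' Applies the model's reference-derived centering, scaling and loadings.
#' Projecting a reference individual reproduces its fitted score.
#'
#' @param model A `"cranio_pca"` from [fit_reference_pca()].
#' @param matrix Complete `"measurement_matrix"` or numeric matrix sharing
#'   the model's measurement set.
#' @param subject_ids Rows to project (default all).
#' @return Numeric matrix (subjects x components).
#' @export
project_test_subjects <- function(model, matrix, subject_ids = NULL) {
  stopifnot(inherits(model, "cranio_pca"))
  x <- if (inherits(matrix, "measurement_matrix")) matrix$values else matrix
  need <- rownames(model$loadings)
  absent <- setdiff(need, colnames(x))
  if (length(absent) > 0) {
    stop("matrix lacks model measurements: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(subject_ids)) subject_ids <- rownames(x)
  missing_ids <- setdiff(subject_ids, rownames(x))
  if (length(missing_ids) > 0) {
    stop("specimens not in matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  sub <- x[subject_ids, need, drop = FALSE]
  if (any(is.na(sub))) stop("matrix must be imputed (complete) before projection",
                            call. = FALSE)
  z <- sweep(sweep(sub, 2, model$center), 2, model$scale, "/")
  z %*% model$loadings
}
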