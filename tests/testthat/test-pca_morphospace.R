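test_that("missingness filtering applies strict thresholds in the requested order", {
  set.seed(61)
  v <- matrix(stats::rnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("S%03d", 1:100), sprintf("M%02d", 1:20)))
  v[1:21, "M01"] <- NA                 # 21% missing measurement -> dropped
  v["S050", 1:3] <- NA                 # 2/19 after M01 drops -> retained
  v["S060", 2:6] <- NA                 # 5/19 = 26% after M01 drops -> dropped
  m <- measurement_matrix(v)
  f <- filter_missingness(m)
  expect_false("M01" %in% colnames(f$values))
  expect_true("S050" %in% rownames(f$values))
  expect_false("S060" %in% rownames(f$values))
  # boundary: a specimen at exactly 15.0% missing is retained ("more than"
  # excluded), one cell above is dropped
  vb <- matrix(stats::rnorm(10 * 20), 10, 20,
               dimnames = list(sprintf("B%02d", 1:10), sprintf("M%02d", 1:20)))
  vb["B01", 1:3] <- NA   # 3/20 = 15.0%
  vb["B02", 1:4] <- NA   # 4/20 = 20%
  fb <- filter_missingness(measurement_matrix(vb))
  expect_true("B01" %in% rownames(fb$values))
  expect_false("B02" %in% rownames(fb$values))

  full <- measurement_matrix(matrix(stats::rnorm(40), 8, 5,
                                    dimnames = list(paste0("S", 1:8), paste0("M", 1:5))))
  expect_identical(filter_missingness(full)$values, full$values)
  expect_identical(filter_missingness(full, order = "SPECIMENS_FIRST")$values,
                   full$values)
  allna <- full
  allna$values[, ] <- NA
  expect_error(filter_missingness(measurement_matrix(allna$values)), "empty")
})

test_that("the nonlinear-only variant runs through the same operations with a class filter", {
  set.seed(62)
  study <- generate_study(synthetic_config(n_test = 2))
  f <- filter_missingness(study$matrix, measurement_max_missing = 0.30,
                          classes = "NONLINEAR")
  expect_true(all(study$matrix$classes[colnames(f$values)] == "NONLINEAR"))
  expect_true(all(colMeans(is.na(f$values)) <= 0.30))
})

test_that("iterative-PCA imputation recovers a rank-1 completion and preserves observed cells", {
  u <- c(1, 2, 3, 4, 5, 6)
  w <- c(2, 1, 4, 3, 5)
  x <- outer(u, w)
  dimnames(x) <- list(paste0("S", 1:6), paste0("M", 1:5))
  x_del <- x
  x_del[2, 3] <- NA
  imp <- impute_iterative_pca(x_del, n_components = 1, scale = FALSE)
  expect_lt(abs(imp[2, 3] - x[2, 3]) / abs(x[2, 3]), 1e-6)
  expect_identical(imp[!is.na(x_del)], x[!is.na(x_del)])
  expect_true(attr(imp, "converged"))

  # fully observed input is returned untouched
  expect_identical(unclass(impute_iterative_pca(x))[seq_along(x)], x[seq_along(x)])

  x_bad <- x_del
  x_bad[1, ] <- NA
  expect_error(impute_iterative_pca(x_bad), "all cells missing")
})

test_that("imputation never alters observed entries on noisy data", {
  set.seed(63)
  x <- matrix(stats::rnorm(200), 20, 10,
              dimnames = list(paste0("S", 1:20), paste0("M", 1:10)))
  x_del <- x
  x_del[sample(length(x), 30)] <- NA
  imp <- impute_iterative_pca(x_del)
  expect_identical(imp[!is.na(x_del)], x[!is.na(x_del)])
  expect_false(anyNA(imp))
})

test_that("reference PCA fit is deterministic, orthonormal, and reproduces fitted scores", {
  set.seed(64)
  x <- matrix(stats::rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("S", 1:30), paste0("M", 1:8)))
  refs <- paste0("S", 1:20)
  model <- fit_reference_pca(x, refs)
  expect_equal(crossprod(model$loadings), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(diff(model$explained_variance) <= 0)
  # duplicated reference list gives the identical model
  model2 <- fit_reference_pca(x, refs)
  expect_identical(model, model2)
  # projecting a reference individual reproduces its fitted score
  z <- sweep(sweep(x[refs, ], 2, model$center), 2, model$scale, "/")
  fitted <- z %*% model$loadings
  expect_equal(project_test_subjects(model, x, "S5"), fitted["S5", , drop = FALSE])
  # a subject at the reference centroid projects to the origin
  x2 <- rbind(x, CENTROID = model$center)
  expect_equal(unname(project_test_subjects(model, x2, "CENTROID")),
               matrix(0, 1, 2))
  expect_error(fit_reference_pca(x, paste0("S", 1:2)), "more reference rows")
  expect_error(project_test_subjects(model, x[, 1:4], "S5"), "lacks")
})

test_that("projection is linear after shared scaling", {
  set.seed(65)
  x <- matrix(stats::rnorm(25 * 6), 25, 6,
              dimnames = list(paste0("S", 1:25), paste0("M", 1:6)))
  model <- fit_reference_pca(x, paste0("S", 1:25))
  a <- 0.3
  mix <- a * x["S1", ] + (1 - a) * x["S2", ]
  x3 <- rbind(x, MIX = mix)
  p <- project_test_subjects(model, x3, c("S1", "S2", "MIX"))
  expect_equal(p["MIX", ], a * p["S1", ] + (1 - a) * p["S2", ])
})

test_that("reference rows on a line are captured by a single component", {
  t <- seq(0, 1, length.out = 10)
  x <- outer(t, c(1, 2, 3, 4)) + matrix(rep(c(5, 6, 7, 8), each = 10), 10, 4)
  dimnames(x) <- list(paste0("S", 1:10), paste0("M", 1:4))
  model <- fit_reference_pca(x, paste0("S", 1:10))
  expect_gt(model$explained_variance[1], 0.999)
})

test_that("synthetic group structure separates in the reference morphospace", {
  set.seed(66)
  study <- generate_study(synthetic_config(n_test = 4))
  filt <- filter_missingness(study$matrix)
  imp <- impute_iterative_pca(filt)
  refs <- intersect(rownames(imp$values),
                    study$records$specimen_id[study$records$group != "TEST"])
  model <- fit_reference_pca(imp, refs)
  coords <- project_test_subjects(model, imp, refs)
  grp <- study$records$group[match(refs, study$records$specimen_id)]
  # mean silhouette over PC1-2 must be positive: groups more compact than mixed
  d <- as.matrix(stats::dist(coords))
  sil <- vapply(seq_along(refs), function(i) {
    a <- mean(d[i, grp == grp[i] & seq_along(refs) != i])
    b <- min(vapply(setdiff(unique(grp), grp[i]),
                    function(g) mean(d[i, grp == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})
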