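test_that("anchor orientation recovers construction signs and flags weak correlations", {
  set.seed(31)
  anchor <- stats::rnorm(500, 100, 10)
  v <- cbind(EKB = anchor,
             DUP = anchor,
             NEG = 200 - anchor,
             IND = stats::rnorm(500))
  rownames(v) <- sprintf("S%03d", 1:500)
  m <- measurement_matrix(v)
  o <- orient_measurements(m)
  expect_equal(unname(o[c("EKB", "DUP", "NEG")]), c(1, 1, -1))
  expect_true("IND" %in% attr(o, "near_zero"))
  expect_error(orient_measurements(m, anchor_measurement = "NOPE"), "anchor")
})

test_that("permuted prediction sets conserve every slot constraint", {
  set.seed(32)
  study <- generate_study(synthetic_config(n_test = 1, missing_rate = 0.15))
  refg <- split(study$records$specimen_id, study$records$group)[c("AMH", "NEANDERTHAL")]
  sp <- study$records$specimen_id[study$records$group == "TEST"][1]
  cmp <- evaluate_predictions(sp, study$profile, study$matrix, refg)
  spec <- permutation_slot_spec(cmp)
  orientation <- orient_measurements(study$matrix)
  observed <- colnames(study$matrix$values)[!is.na(study$matrix$values[sp, ])]
  pool <- split(observed, study$matrix$classes[observed])
  for (i in 1:500) {
    perm <- sample_permuted_profile(spec, pool, orientation)
    expect_equal(nrow(perm), attr(spec, "k_total"))
    expect_equal(table(factor(perm$reference_group, c("AMH", "NEANDERTHAL"))),
                 attr(spec, "k_by_reference"))
    expect_equal(table(factor(perm$measurement_class, c("LINEAR", "NONLINEAR"))),
                 attr(spec, "k_by_class"))
    expect_false(anyDuplicated(perm$measurement_id) > 0)
    expect_true(all(perm$direction %in% c(-1L, 1L)))
    # effective direction = slot direction x orientation of the draw
    expect_equal(perm$direction,
                 as.integer(spec$direction * orientation[perm$measurement_id]))
  }
})

test_that("a pool of exactly the required size forces the single possible draw", {
  spec_df <- data.frame(prediction_id = c("P1", "P2"),
                        reference_group = "AMH",
                        measurement_class = "LINEAR",
                        direction = c(1L, -1L), stringsAsFactors = FALSE)
  attr(spec_df, "k_total") <- 2L
  attr(spec_df, "k_by_reference") <- table(factor(spec_df$reference_group,
                                                  c("AMH", "NEANDERTHAL")))
  attr(spec_df, "k_by_class") <- table(factor(spec_df$measurement_class,
                                              c("LINEAR", "NONLINEAR")))
  class(spec_df) <- c("permutation_slot_spec", "data.frame")
  orientation <- c(M1 = 1, M2 = 1)
  for (i in 1:10) {
    perm <- sample_permuted_profile(spec_df, list(LINEAR = c("M1", "M2")), orientation)
    expect_setequal(perm$measurement_id, c("M1", "M2"))
  }
  expect_error(sample_permuted_profile(spec_df, list(LINEAR = "M1"), orientation),
               "exhausted")
})

test_that("pool restricted to exchangeable profile measurements gives p_raw = 1", {
  # all slots share reference, class and direction, and every measurement
  # is positively oriented, so each permutation reproduces the observed
  # comparison set and ties count toward the numerator
  set.seed(33)
  n_ref <- 8
  ids <- c(paste0("A", seq_len(n_ref)), "EKB_HOST", "SUBJ")
  base <- stats::rnorm(length(ids), 100, 5)
  v <- cbind(EKB = base,
             M1 = base + stats::rnorm(length(ids), 0, 2),
             M2 = base + stats::rnorm(length(ids), 0, 2))
  rownames(v) <- ids
  m <- measurement_matrix(v)
  prof <- mini_profile(c("M1", "M2"), direction = c(1L, 1L))
  refg <- list(AMH = paste0("A", seq_len(n_ref)),
               NEANDERTHAL = paste0("A", seq_len(n_ref)))
  res <- permutation_test("SUBJ", prof, m, refg, n_perm = 50,
                          pool_measurements = c("M1", "M2"))
  expect_equal(res$p_raw, 1)
})

test_that("an extreme planted subject attains p_raw = 0", {
  set.seed(34)
  study <- generate_study(synthetic_config(n_test = 0, missing_rate = 0))
  study <- plant_denisovan_like(study, 50)
  refg <- split(study$records$specimen_id, study$records$group)[c("AMH", "NEANDERTHAL")]
  res <- permutation_test("PLANTED", study$profile, study$matrix, refg, n_perm = 200)
  expect_equal(res$p_raw, 0)
  expect_true(all(res$permuted_combined < res$observed_combined))
  # add-one smoothing stays available behind its flag
  set.seed(34)
  res1 <- permutation_test("PLANTED", study$profile, study$matrix, refg,
                           n_perm = 200, add_one = TRUE)
  expect_equal(res1$p_raw, 1 / 201)
})

test_that("permutation results are reproducible bit-for-bit under a fixed seed", {
  study <- local({ set.seed(35); generate_study(synthetic_config(n_test = 1)) })
  refg <- split(study$records$specimen_id, study$records$group)[c("AMH", "NEANDERTHAL")]
  sp <- study$records$specimen_id[study$records$group == "TEST"][1]
  set.seed(99)
  a <- permutation_test(sp, study$profile, study$matrix, refg, n_perm = 100)
  set.seed(99)
  b <- permutation_test(sp, study$profile, study$matrix, refg, n_perm = 100)
  expect_identical(a, b)
  expect_error(permutation_test(sp, study$profile, study$matrix, refg, n_perm = 0),
               "n_perm")
})

test_that("raising the planted effect never raises the permutation p-value", {
  for (seed in c(41, 42)) {
    p_by_effect <- vapply(c(0.5, 1.5, 3), function(eff) {
      set.seed(seed)
      study <- generate_study(synthetic_config(n_test = 0))
      study <- plant_denisovan_like(study, eff)
      refg <- split(study$records$specimen_id, study$records$group)[c("AMH", "NEANDERTHAL")]
      set.seed(seed + 1000)
      permutation_test("PLANTED", study$profile, study$matrix, refg,
                       n_perm = 300)$p_raw
    }, numeric(1))
    expect_true(all(diff(p_by_effect) <= 0))
  }
})

test_that("batched permutation tests BH-adjust the qualifying family only", {
  set.seed(36)
  study <- generate_study(synthetic_config(n_test = 3, missing_rate = 0.05))
  study <- plant_denisovan_like(study, 1.5)
  set.seed(37)
  tab <- run_permutation_tests(study$matrix, study$records, study$profile,
                               n_perm = 50)
  expect_setequal(tab$specimen_id,
                  study$records$specimen_id[study$records$group == "TEST"])
  fam <- tab$n_tested >= 5
  expect_true(all(!is.na(tab$p_adjusted[fam])))
  expect_true(all(tab$p_adjusted[fam] >= tab$p_raw[fam] - 1e-12))
  expect_equal(tab$p_adjusted[tab$specimen_id == "PLANTED"],
               min(tab$p_adjusted, na.rm = TRUE))
})
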