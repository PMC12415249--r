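# End-to-end pipeline wiring: configuration, stage runners, run manifest.
#
# The analysis/ scripts in the repository are thin drivers over these
# functions; everything they compute lives here so tests can exercise it.

#' Build a run configuration
#'
#' @param matrix A `"measurement_matrix"` (or path readable by
#'   [read_measurement_matrix()] together with `dialect`).
#' @param records Specimen records data.frame.
#' @param profile Prediction profile (or path for [load_profile()]).
#' @param mode `"RAW"` (default) or `"NORMALIZED"` (divide linear
#'   measurements by cube-root cranial capacity; requires capacities).
#' @param n_perm Permutations per subject.
#' @param seed Integer seed recorded in every output.
#' @param min_testable Testable-prediction threshold for test subjects and
#'   the BH family.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param dialect Dialect when `matrix` is a path.
#' @return A validated `"run_config"` list.
#' @export
run_config <- function(matrix, records, profile = load_profile(),
                       mode = c("RAW", "NORMALIZED"), n_perm = 10000L,
                       seed = 1L, min_testable = 5L, out_dir = NULL,
                       dialect = "CSV") {
  mode <- match.arg(mode)
  if (is.character(matrix)) matrix <- read_measurement_matrix(matrix, dialect)
  if (is.character(profile)) profile <- load_profile(profile)
  stopifnot(inherits(matrix, "measurement_matrix"),
            is.data.frame(records))
  if (mode == "NORMALIZED" && is.null(matrix$capacity)) {
    stop("NORMALIZED mode requires cranial capacities in the matrix", call. = FALSE)
  }
  if (!"n_testable" %in% names(records) || any(is.na(records$n_testable))) {
    records$n_testable <- count_testable(matrix, profile)[records$specimen_id]
  }
  structure(list(matrix = matrix, records = records, profile = profile,
                 mode = mode, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), min_testable = as.integer(min_testable),
                 out_dir = out_dir),
            class = "run_config")
}

working_matrix <- function(config) {
  if (config$mode == "NORMALIZED") normalize_by_cranial_capacity(config$matrix)
  else config$matrix
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(values = config$matrix$values, mode = config$mode,
               n_perm = config$n_perm, seed = config$seed,
               min_testable = config$min_testable,
               profile = as.data.frame(config$profile)),
          f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

write_stage <- function(df, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, paste0(name, ".tsv"))
  header <- sprintf("# seed=%d config=%s", config$seed, config_hash(config))
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}

#' Run the scoring stage
#'
#' Scores every usable specimen (selected test subjects plus leave-one-out
#' reference controls) against the profile. Deterministic given inputs.
#'
#' @param config A [run_config()].
#' @return Score table (see [score_specimens()]).
#' @export
run_score <- function(config) {
  stopifnot(inherits(config, "run_config"))
  matrix <- working_matrix(config)
  records <- select_test_subjects(config$records, config$min_testable)
  scores <- score_specimens(matrix, records, config$profile)
  write_stage(scores, config, "scores")
  scores
}

#' Run the permutation stage
#'
#' Constraint-preserving permutation tests for every selected test
#' subject, with BH adjustment across subjects having at least
#' `min_testable` testable predictions. Seeded from `config$seed`.
#'
#' @param config A [run_config()].
#' @return Permutation table (see [run_permutation_tests()]).
#' @export
run_permute <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  matrix <- working_matrix(config)
  records <- select_test_subjects(config$records, config$min_testable)
  perms <- run_permutation_tests(matrix, records, config$profile,
                                 n_perm = config$n_perm,
                                 min_testable = config$min_testable)
  perms$seed <- config$seed
  write_stage(perms, config, "permutations")
  perms
}

#' Run the full pipeline
#'
#' score -> permute -> differentiate (top subjects) -> PCA morphospace ->
#' mandibular validation summary, with a machine-readable run manifest.
#'
#' @param config A [run_config()].
#' @param top_n Number of top-scoring test subjects carried into the
#'   differentiation stage (default 3).
#' @return List of stage outputs plus `manifest`.
#' @export
run_all <- function(config, top_n = 3L) {
  stopifnot(inherits(config, "run_config"))
  stages <- c("score", "permute", "differentiate", "pca", "validate")
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  scores <- run_stage("score", run_score(config))
  perms <- run_stage("permute", run_permute(config))
  test_scores <- scores[scores$group == "TEST", ]
  top <- test_scores$specimen_id[order(-test_scores$combined_score)]
  top <- utils::head(top, top_n)
  matrix <- working_matrix(config)
  records <- select_test_subjects(config$records, config$min_testable)
  diff_tab <- run_stage("differentiate",
                        differentiate_subjects(top, matrix, records, config$profile))
  write_stage(diff_tab, config, "differentiation")
  pca_tab <- run_stage("pca", {
    filtered <- filter_missingness(matrix)
    imputed <- impute_iterative_pca(filtered)
    ref_ids <- intersect(rownames(imputed$values),
                         records$specimen_id[records$group != "TEST"])
    model <- fit_reference_pca(imputed, ref_ids)
    coords <- project_test_subjects(model, imputed)
    data.frame(specimen_id = rownames(coords),
               group = records$group[match(rownames(coords), records$specimen_id)],
               PC1 = coords[, 1], PC2 = coords[, 2],
               stringsAsFactors = FALSE)
  })
  write_stage(pca_tab, config, "pca")
  validation <- run_stage("validate", {
    checks <- evaluate_mandibular_checks()
    harbin <- scores[scores$specimen_id == "Harbin", ]
    if (nrow(harbin) == 1) {
      validation_summary(checks, extra_confirmed = harbin$n_positive,
                         extra_testable = harbin$n_tested)
    } else {
      validation_summary(checks)
    }
  })
  manifest <- list(package_version = as.character(utils::packageVersion("deniscan")),
                   seed = config$seed, mode = config$mode,
                   n_perm = config$n_perm, config_hash = config_hash(config),
                   stages = stages)
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(scores = scores, permutations = perms, differentiation = diff_tab,
       pca = pca_tab, validation = validation, manifest = manifest)
}
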