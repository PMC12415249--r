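# Synthetic craniometric study generator.
#
# Emulates the statistical structure the scan assumes: three reference
# groups (20 H. erectus, 18 H. sapiens, 15 Neanderthals) plus test
# subjects; ~150 continuous measurements correlated through a latent size
# factor (most of them positively with the biorbital-breadth anchor EKB, a
# minority negatively) and through a handful of low-rank "anatomical
# region" factors plus diagonal noise; group mean shifts; optional planted
# Denisovan-like specimens with configurable signed effect sizes on the
# profile measurements; and missing-at-random entries mimicking
# differential preservation.
#
# Measurement model for specimen i, measurement j:
#   x_ij = mu_j + beta_j * size_i + gamma_j * f_region(j),i
#          + delta_{g(i),j} * sigma_within_j + eps_ij
# with size_i ~ N(group size mean, 1), f ~ N(group factor mean, 1),
# eps ~ N(0, sigma_j^2). Group shifts delta are expressed in within-group
# SD units. Nonlinear measurements (angles/ratios) carry zero size loading.

#' Default synthetic study configuration
#'
#' @param n_erectus,n_amh,n_nea Reference group sizes (defaults 20/18/15).
#' @param n_test Number of null test subjects (default 10).
#' @param n_measurements Total measurement count (default 150: 126 linear of
#'   which 24 negatively size-loaded, 24 nonlinear).
#' @param n_negative Linear measurements with negative anchor correlation.
#' @param n_nonlinear Nonlinear (angle/ratio) measurements.
#' @param missing_rate Missing-at-random cell deletion rate (default 0.10).
#' @param test_base_group Distribution the null test subjects are drawn
#'   from (default `"H_ERECTUS"`, archaic crania).
#' @param n_factors Number of anatomical-region factors (default 3).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_erectus = 20L, n_amh = 18L, n_nea = 15L,
                             n_test = 10L, n_measurements = 150L,
                             n_negative = 24L, n_nonlinear = 24L,
                             missing_rate = 0.10,
                             test_base_group = "H_ERECTUS",
                             n_factors = 3L) {
  stopifnot(n_erectus >= 0, n_amh >= 3, n_nea >= 3, n_test >= 0,
            missing_rate >= 0, missing_rate < 1,
            n_measurements >= 13 + n_nonlinear,
            n_nonlinear >= 2, n_negative >= 0,
            test_base_group %in% c("AMH", "NEANDERTHAL", "H_ERECTUS"))
  structure(list(n_erectus = n_erectus, n_amh = n_amh, n_nea = n_nea,
                 n_test = n_test, n_measurements = n_measurements,
                 n_negative = n_negative, n_nonlinear = n_nonlinear,
                 missing_rate = missing_rate,
                 test_base_group = test_base_group,
                 n_factors = n_factors),
            class = "synthetic_config")
}

# Measurement-level parameters implied by a config: names, classes, size
# loadings, factor loadings, noise SDs, baselines, and the per-group shift
# pattern (in within-group SD units). Deterministic given the RNG state.
synthetic_parameters <- function(config) {
  profile <- load_profile()
  profile_meas <- unique(profile$measurement_id)
  profile_class <- profile$measurement_class[match(profile_meas, profile$measurement_id)]
  nl_profile <- profile_meas[profile_class == "NONLINEAR"]
  lin_profile <- profile_meas[profile_class == "LINEAR"]
  n_lin_fill <- config$n_measurements - config$n_nonlinear - length(lin_profile) - 1L
  n_nl_fill <- config$n_nonlinear - length(nl_profile)
  meas <- c("EKB", lin_profile,
            sprintf("LM%03d", seq_len(n_lin_fill)),
            nl_profile,
            sprintf("NM%03d", seq_len(n_nl_fill)))
  classes <- stats::setNames(
    c(rep("LINEAR", 1 + length(lin_profile) + n_lin_fill),
      rep("NONLINEAR", length(nl_profile) + n_nl_fill)), meas)
  n_m <- length(meas)
  is_linear <- classes == "LINEAR"
  # size loadings: strong positive anchor; most linear positive, a fixed
  # minority of linear fillers negative; nonlinear (angles/ratios) only
  # weakly size-coupled, half of them negatively
  beta <- stats::setNames(numeric(n_m), meas)
  beta[is_linear] <- stats::runif(sum(is_linear), 0.5, 1.2)
  beta["EKB"] <- 1.2
  nl <- meas[!is_linear]
  beta[nl] <- stats::runif(length(nl), 0.15, 0.35) *
    rep_len(c(1, -1), length(nl))
  beta[c("FPA", "MFI")] <- abs(beta[c("FPA", "MFI")])
  neg_pool <- grep("^LM", meas, value = TRUE)
  neg <- neg_pool[seq_len(min(config$n_negative, length(neg_pool)))]
  beta[neg] <- -beta[neg]
  # anatomical-region factors
  region <- stats::setNames(sample.int(config$n_factors, n_m, replace = TRUE), meas)
  gamma <- stats::setNames(stats::runif(n_m, 0.3, 0.6), meas)
  sigma <- stats::setNames(stats::runif(n_m, 0.4, 0.7), meas)
  mu <- stats::setNames(stats::runif(n_m, 40, 180), meas)
  sd_within <- sqrt(beta^2 + gamma^2 + sigma^2)
  # Group shift pattern (within-group SD units, relative to AMH). Under
  # the null the profile measurements must be statistically exchangeable
  # with random draws from the pool, so group structure is carried only by
  # channels the permutation design conserves: the latent size factor
  # (linear measurements; Neanderthals large, H. erectus small), an
  # orientation-aligned "archaic robusticity" shift shared by ALL
  # nonlinear measurements (Neanderthals high on positively size-coupled
  # angles/indices, low on negatively coupled ones), and small
  # idiosyncratic per-measurement shifts. Denisovan-specific directional
  # signal exists only in planted specimens.
  delta <- matrix(0, nrow = 3, ncol = n_m,
                  dimnames = list(c("AMH", "NEANDERTHAL", "H_ERECTUS"), meas))
  delta["NEANDERTHAL", ] <- stats::rnorm(n_m, 0, 0.3)
  delta["H_ERECTUS", ] <- stats::rnorm(n_m, 0, 0.3)
  delta["NEANDERTHAL", nl] <- delta["NEANDERTHAL", nl] + 0.7 * sign(beta[nl])
  # group latent means give the size structure and morphospace separation
  size_mean <- c(AMH = 0, NEANDERTHAL = 0.5, H_ERECTUS = -0.5)
  factor_mean <- rbind(AMH = rep(0, config$n_factors),
                       NEANDERTHAL = c(0.8, -0.8, rep(0.4, config$n_factors - 2)),
                       H_ERECTUS = c(-1.2, 0.8, rep(-0.6, config$n_factors - 2)))
  list(measurements = meas, classes = classes, beta = beta, gamma = gamma,
       region = region, sigma = sigma, mu = mu, sd_within = sd_within,
       delta = delta, size_mean = size_mean, factor_mean = factor_mean,
       profile = profile)
}

draw_specimens <- function(params, group, n, prefix, config) {
  meas <- params$measurements
  n_m <- length(meas)
  out <- matrix(NA_real_, n, n_m, dimnames = list(sprintf("%s%02d", prefix, seq_len(n)), meas))
  for (i in seq_len(n)) {
    size <- stats::rnorm(1, params$size_mean[[group]], 1)
    f <- stats::rnorm(config$n_factors, params$factor_mean[group, ], 1)
    eps <- stats::rnorm(n_m, 0, params$sigma)
    out[i, ] <- params$mu + params$beta * size + params$gamma * f[params$region] +
      params$delta[group, ] * params$sd_within + eps
  }
  out
}

#' Generate a synthetic craniometric study
#'
#' Produces a measurement matrix (reference groups plus null test
#' subjects), specimen records, and the prediction profile the matrix was
#' built to carry (the packaged default profile; all its measurements exist
#' in the matrix). Reproducible from the RNG state: call `set.seed()`
#' first.
#'
#' @param config A [synthetic_config()].
#' @return List with `matrix` (a `"measurement_matrix"`), `records`
#'   (specimen `data.frame`), `profile`, and `params` (the generating
#'   parameters, for oracle checks).
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  params <- synthetic_parameters(config)
  blocks <- list(
    draw_specimens(params, "H_ERECTUS", config$n_erectus, "ERE", config),
    draw_specimens(params, "AMH", config$n_amh, "AMH", config),
    draw_specimens(params, "NEANDERTHAL", config$n_nea, "NEA", config)
  )
  groups <- rep(c("H_ERECTUS", "AMH", "NEANDERTHAL"),
                c(config$n_erectus, config$n_amh, config$n_nea))
  if (config$n_test > 0) {
    blocks <- c(blocks, list(draw_specimens(params, config$test_base_group,
                                            config$n_test, "TST", config)))
    groups <- c(groups, rep("TEST", config$n_test))
  }
  values <- do.call(rbind, blocks)
  mat <- new_measurement_matrix(values, params$classes)
  if (config$missing_rate > 0) {
    mat <- inject_missingness(mat, config$missing_rate, pattern = "MCAR")
  }
  records <- data.frame(specimen_id = rownames(mat$values),
                        group = groups,
                        is_adult = TRUE,
                        stringsAsFactors = FALSE)
  records$n_testable <- count_testable(mat, params$profile)[records$specimen_id]
  list(matrix = mat, records = records, profile = params$profile, params = params)
}

#' Append a planted Denisovan-like specimen
#'
#' Draws one specimen from the base group's distribution and shifts each
#' profile measurement in the predicted Denisovan direction by
#' `effect_sd_units` within-group (empirical base-group) standard
#' deviations. For measurements carrying two predictions with opposite
#' signs (Neanderthal-derived phenotypes, where the Denisovan is predicted
#' above the AMH median but below the Neanderthal one), the planted value
#' is placed at the midpoint of the two reference-group medians when that
#' interval is nonempty; otherwise the literal shift rule applies using the
#' AMH-referenced direction.
#'
#' @param study A study list from [generate_study()].
#' @param effect_sd_units Planted effect size in within-group SD units.
#' @param base_group Group whose distribution the specimen is drawn from.
#'   Defaults to `"NEANDERTHAL"`: Denisovans are the Neanderthal sister
#'   lineage, so a Denisovan-like specimen is a Neanderthal-distributed
#'   craniun displaced toward the predicted Denisovan state.
#' @param specimen_id ID for the planted specimen.
#' @return The study with the specimen appended to `matrix` and `records`
#'   (group `"TEST"`, fully observed).
#' @export
plant_denisovan_like <- function(study, effect_sd_units, base_group = "NEANDERTHAL",
                                 specimen_id = "PLANTED") {
  params <- study$params
  profile <- study$profile
  values <- study$matrix$values
  if (specimen_id %in% rownames(values)) {
    stop("specimen ID already present: ", specimen_id, call. = FALSE)
  }
  draw <- draw_specimens(params, base_group, 1L, "TMP",
                         list(n_factors = ncol(params$factor_mean)))[1, ]
  group_of <- function(g) rownames(values)[startsWith(rownames(values),
                                                      c(AMH = "AMH", NEANDERTHAL = "NEA", H_ERECTUS = "ERE")[g])]
  for (m in unique(profile$measurement_id)) {
    preds <- profile[profile$measurement_id == m, ]
    sd_base <- stats::sd(values[group_of(base_group), m], na.rm = TRUE)
    if (!is.finite(sd_base) || sd_base == 0) sd_base <- params$sd_within[[m]]
    if (nrow(preds) == 2 && length(unique(preds$direction)) == 2) {
      med <- vapply(preds$reference_group, function(r) {
        stats::median(values[group_of(r), m], na.rm = TRUE)
      }, numeric(1))
      lo_side <- preds$reference_group[preds$direction == 1]
      hi_side <- preds$reference_group[preds$direction == -1]
      lo <- med[[lo_side]]; hi <- med[[hi_side]]
      if (lo < hi) {
        draw[m] <- (lo + hi) / 2
        next
      }
    }
    s <- preds$direction[match("AMH", preds$reference_group)]
    if (is.na(s)) s <- preds$direction[1]
    draw[m] <- draw[m] + s * effect_sd_units * sd_base
  }
  values <- rbind(values, draw)
  rownames(values)[nrow(values)] <- specimen_id
  study$matrix <- new_measurement_matrix(values, study$matrix$classes,
                                         study$matrix$capacity)
  rec <- data.frame(specimen_id = specimen_id, group = "TEST", is_adult = TRUE,
                    n_testable = NA_integer_, stringsAsFactors = FALSE)
  rec$n_testable <- count_testable(study$matrix, profile)[specimen_id]
  study$records <- rbind(study$records, rec)
  study
}

#' Inject missingness into a measurement matrix
#'
#' `"MCAR"` deletes cells uniformly at random at the given rate.
#' `"PRESERVATION_BLOCKS"` emulates differential preservation: for each
#' specimen, whole contiguous runs of measurement columns (anatomical
#' regions) are deleted until the target per-specimen rate is reached.
#'
#' @param matrix A `"measurement_matrix"`.
#' @param rate Target missing fraction in `[0, 1)`.
#' @param pattern `"MCAR"` or `"PRESERVATION_BLOCKS"`.
#' @param n_blocks Maximum deleted blocks per specimen (block pattern).
#' @return The matrix with additional missing cells.
#' @export
inject_missingness <- function(matrix, rate,
                               pattern = c("MCAR", "PRESERVATION_BLOCKS"),
                               n_blocks = 3L) {
  pattern <- match.arg(pattern)
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(matrix)
  values <- matrix$values
  if (pattern == "MCAR") {
    drop <- stats::runif(length(values)) < rate
    values[drop] <- NA_real_
  } else {
    n_m <- ncol(values)
    target <- round(rate * n_m)
    for (i in seq_len(nrow(values))) {
      if (target < 1) next
      sizes <- diff(c(0, sort(sample.int(target, min(n_blocks, target) - 1L)), target))
      sizes <- sizes[sizes > 0]
      for (len in sizes) {
        start <- sample.int(n_m - len + 1L, 1)
        values[i, start:(start + len - 1L)] <- NA_real_
      }
    }
  }
  new_measurement_matrix(values, matrix$classes, matrix$capacity)
}
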