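# Shared fixture builders. Everything is generated in code; no binary data.

# A tiny deterministic measurement matrix with one missing cell.
tiny_matrix <- function() {
  v <- matrix(c(10, 20, 30,
                40, NA, 60), nrow = 3, ncol = 2,
              dimnames = list(c("S1", "S2", "S3"), c("M1", "M2")))
  measurement_matrix(v)
}

# Reference matrix where a specimen can be placed exactly at the median.
# n_ref odd so the median is an observed value.
median_fixture <- function(n_ref = 5) {
  ref_vals <- seq_len(n_ref) * 10
  v <- rbind(matrix(ref_vals, nrow = n_ref, ncol = 2,
                    dimnames = list(paste0("A", seq_len(n_ref)),
                                    c("M1", "M2"))),
             SUBJ = rep(stats::median(ref_vals), 2))
  list(matrix = measurement_matrix(v),
       reference_groups = list(AMH = paste0("A", seq_len(n_ref)),
                               NEANDERTHAL = paste0("A", seq_len(n_ref))))
}

# Minimal two-prediction profile against AMH only.
mini_profile <- function(measurements = c("M1", "M2"), direction = c(1L, 1L),
                         reference = "AMH", class = "LINEAR") {
  p <- data.frame(prediction_id = paste0("T", seq_along(measurements)),
                  phenotype_id = paste0("ph", seq_along(measurements)),
                  measurement_id = measurements,
                  reference_group = reference,
                  direction = direction,
                  lineage_origin = "AMH_DERIVED",
                  measurement_class = class,
                  stringsAsFactors = FALSE)
  class(p) <- c("denisovan_profile", "data.frame")
  p
}

# Independent brute-force quantile oracle: plotting positions (i - 0.5)/N
# with tied values sharing the mean, written without the CDF structure.
brute_support_quantiles <- function(values) {
  n <- length(values)
  sorted <- sort(values)
  vapply(sorted, function(v) {
    idx <- which(sorted == v)
    mean((idx - 0.5) / n)
  }, numeric(1))
}

# Independent binomial mid-p oracle: enumerate all 2^k equally likely
# match/mismatch sequences.
brute_binomial_midp <- function(n_pos, k) {
  counts <- rowSums(as.matrix(expand.grid(rep(list(0:1), k))))
  (sum(counts > n_pos) + 0.5 * sum(counts == n_pos)) / 2^k
}

# Independent signed-rank oracle: dynamic programming over the exact
# distribution of the positive-rank sum for tie-free integer ranks.
brute_signed_rank_p <- function(distances) {
  stopifnot(all(distances != 0), !anyDuplicated(abs(distances)))
  r <- rank(abs(distances))
  w_obs <- sum(r[distances > 0])
  w_max <- sum(r)
  dist <- c(1, rep(0, w_max)) # dist[w + 1] = #assignments with sum w
  for (ri in r) {
    shifted <- c(rep(0, ri), dist[seq_len(length(dist) - ri)])
    dist <- dist + shifted
  }
  sum(dist[(w_obs + 1):(w_max + 1)]) / 2^length(r)
}
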