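#!/usr/bin/env Rscript
# Stage 3: constraint-preserving permutation test for every test subject,
# with BH adjustment across the subjects having at least five testable
# predictions. The planted Denisovan-like subject should be the only one
# with a significant adjusted p-value.

suppressPackageStartupMessages(library(deniscan))

data_dir <- "results/data"
mat <- read_measurement_matrix(file.path(data_dir, "measurements.csv"), "CSV",
                               class_sidecar = file.path(data_dir, "measurement_classes.tsv"))
records <- utils::read.delim(file.path(data_dir, "records.tsv"))
profile <- load_profile(file.path(data_dir, "profile.tsv"))

config <- run_config(mat, records, profile, n_perm = 2000L,
                     seed = as.integer(readLines(file.path(data_dir, "seed.txt"))),
                     out_dir = "results")
perms <- run_permute(config)

print(perms[order(perms$p_adjusted), ], row.names = FALSE, digits = 3)
sig <- perms$specimen_id[!is.na(perms$p_adjusted) & perms$p_adjusted < 0.05]
cat("\nSubjects with adjusted p < 0.05:", paste(sig, collapse = ", "), "\n")
cat("Wrote results/permutations.tsv\n")
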