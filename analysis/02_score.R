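#!/usr/bin/env Rscript
# Stage 2: score every specimen against the Denisovan profile — test
# subjects against the AMH/Neanderthal reference distributions, reference
# specimens leave-one-out as controls — and report the ranking.

suppressPackageStartupMessages(library(deniscan))

data_dir <- "results/data"
mat <- read_measurement_matrix(file.path(data_dir, "measurements.csv"), "CSV",
                               class_sidecar = file.path(data_dir, "measurement_classes.tsv"))
records <- utils::read.delim(file.path(data_dir, "records.tsv"))
profile <- load_profile(file.path(data_dir, "profile.tsv"))

config <- run_config(mat, records, profile,
                     seed = as.integer(readLines(file.path(data_dir, "seed.txt"))),
                     out_dir = "results")
scores <- run_score(config)

top <- scores[order(-scores$combined_score), ][1:5, ]
cat("Top 5 combined scores:\n")
print(top[, c("specimen_id", "group", "n_positive", "n_tested",
              "binomial_score", "wilcoxon_score", "combined_score")],
      row.names = FALSE, digits = 3)
cat("\nGroup median combined scores:\n")
print(aggregate(combined_score ~ group, scores, stats::median), row.names = FALSE)
cat("\nWrote results/scores.tsv\n")
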