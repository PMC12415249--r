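#!/usr/bin/env Rscript
# Stage 4: re-score the top-ranking subjects using only the predictions
# that distinguish Denisovans from Neanderthals, and place their combined
# scores within the leave-one-out Neanderthal score distribution.

suppressPackageStartupMessages(library(deniscan))

data_dir <- "results/data"
mat <- read_measurement_matrix(file.path(data_dir, "measurements.csv"), "CSV",
                               class_sidecar = file.path(data_dir, "measurement_classes.tsv"))
records <- utils::read.delim(file.path(data_dir, "records.tsv"))
profile <- load_profile(file.path(data_dir, "profile.tsv"))

scores <- utils::read.delim("results/scores.tsv", comment.char = "#")
test_scores <- scores[scores$group == "TEST", ]
top <- test_scores$specimen_id[order(-test_scores$combined_score)][1:3]
cat("Differentiating top subjects:", paste(top, collapse = ", "), "\n\n")

tab <- differentiate_subjects(top, mat, records, profile)
print(tab[, c("specimen_id", "n_positive", "n_tested", "combined_score",
              "neanderthal_percentile")], row.names = FALSE, digits = 3)
utils::write.table(tab, "results/differentiation.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("\nWrote results/differentiation.tsv\n")
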