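#!/usr/bin/env Rscript
# Stage 1: simulate a synthetic craniometric study with the design of the
# cranial scan (20 H. erectus, 18 H. sapiens, 15 Neanderthals, 9 null
# archaic test subjects) and plant one Denisovan-like specimen at a
# 1.5-SD effect on the profile measurements. Writes the matrix, the
# specimen records and the profile in the formats the package readers
# accept.

suppressPackageStartupMessages(library(deniscan))

seed <- 20260922L
set.seed(seed)
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- generate_study(synthetic_config(n_test = 9))
study <- plant_denisovan_like(study, effect_sd_units = 1.5)

write_measurement_matrix(study$matrix, file.path(out, "measurements.csv"), "CSV")
utils::write.table(data.frame(measurement_id = names(study$matrix$classes),
                              class = unname(study$matrix$classes)),
                   file.path(out, "measurement_classes.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(study$records, file.path(out, "records.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
invisible(file.copy(default_profile_path(), file.path(out, "profile.tsv"),
                    overwrite = TRUE))
writeLines(as.character(seed), file.path(out, "seed.txt"))

cat(sprintf("Simulated %d specimens x %d measurements (%.1f%% missing), planted subject 'PLANTED'.\n",
            nrow(study$matrix$values), ncol(study$matrix$values),
            100 * mean(is.na(study$matrix$values))))
cat("Wrote", out, "\n")
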