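#!/usr/bin/env Rscript
# Stage 6: mandibular validation. Evaluates the packaged table of
# published Xiahe 1 / Penghu 1 mandibular checks against the directional
# predictions and pools the tally with the Harbin cranium's 16/18.

suppressPackageStartupMessages(library(deniscan))

checks <- evaluate_mandibular_checks()
print(checks[, c("specimen", "prediction_id", "predicted_direction",
                 "observed_value", "comparator_value", "outcome")],
      row.names = FALSE)

s <- validation_summary(checks, extra_confirmed = 16L, extra_testable = 18L)
cat("\nPer specimen:\n")
print(s$per_specimen, row.names = FALSE)
cat(sprintf("\nMandibular predictions confirmed: %d/%d (%d%%)\n",
            s$confirmed, s$testable, s$percent))
cat(sprintf("Pooled with the Harbin cranium: %d/%d (%d%%)\n",
            s$pooled_confirmed, s$pooled_testable, s$pooled_percent))

dir.create("results", showWarnings = FALSE)
utils::write.table(checks, "results/mandible_checks.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("Wrote results/mandible_checks.tsv\n")
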