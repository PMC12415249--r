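#!/usr/bin/env Rscript
# Stage 5: morphospace. Filter by missingness (measurements with > 20%
# missing, then specimens with > 15%), impute by iterative PCA, fit the
# two-component PCA on the reference individuals only, and project the
# test subjects onto that plane.

suppressPackageStartupMessages(library(deniscan))

data_dir <- "results/data"
mat <- read_measurement_matrix(file.path(data_dir, "measurements.csv"), "CSV",
                               class_sidecar = file.path(data_dir, "measurement_classes.tsv"))
records <- utils::read.delim(file.path(data_dir, "records.tsv"))

filtered <- filter_missingness(mat)
imputed <- impute_iterative_pca(filtered)
refs <- intersect(rownames(imputed$values),
                  records$specimen_id[records$group != "TEST"])
model <- fit_reference_pca(imputed, refs)
coords <- project_test_subjects(model, imputed)

tab <- data.frame(specimen_id = rownames(coords),
                  group = records$group[match(rownames(coords), records$specimen_id)],
                  PC1 = coords[, 1], PC2 = coords[, 2])
utils::write.table(tab, "results/pca.tsv", sep = "\t", row.names = FALSE,
                   quote = FALSE)

cat(sprintf("PCA on %d measurements, %d specimens; PC1/PC2 explain %.1f%% / %.1f%% of reference variance.\n",
            nrow(model$loadings), nrow(coords),
            100 * model$explained_variance[1], 100 * model$explained_variance[2]))
cat("Reference group centroids (PC1, PC2):\n")
print(aggregate(cbind(PC1, PC2) ~ group, tab[tab$group != "TEST", ], mean),
      row.names = FALSE, digits = 3)
cat("Test subjects:\n")
print(tab[tab$group == "TEST", ], row.names = FALSE, digits = 3)
cat("Wrote results/pca.tsv\n")
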