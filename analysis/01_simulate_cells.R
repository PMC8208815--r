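#!/usr/bin/env Rscript
# Simulate the recorded-cell cohorts: two genotypes, three progenitor
# stages, patch-clamp biophysics per cell, a minority of marker-labeled
# cells, and QC fields. Writes the cohort and its ground truth.

suppressPackageStartupMessages(library(sgzephys))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

sim <- generate_cells(generator_config(seed = seed, n_cells = 200))
write_cell_table(sim$records, "results/cells_raw.csv")
write.csv(sim$truth, "results/cells_truth.csv", row.names = FALSE)

qc <- qc_filter(sim$records)
write_cell_table(qc$kept, "results/cells_qc_passed.csv")
write.csv(qc$excluded[, c("cell_id", "qc_reason")],
          "results/cells_qc_excluded.csv", row.names = FALSE)

cat(sprintf("simulated %d cells (%d per genotype), seed %d\n",
            nrow(sim$records), 200L, seed))
cat(sprintf("QC: kept %d, excluded %d (%s)\n",
            nrow(qc$kept), nrow(qc$excluded),
            paste(unique(qc$excluded$qc_reason), collapse = ", ")))
cat(sprintf("labeled cells: %d of %d\n",
            sum(!is.na(sim$records$known_type)), nrow(sim$records)))
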