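#!/usr/bin/env Rscript
# Stage 2: cell-level quality control on both modalities.
#
# Applies the strict printed filters (400 < nFeatures < 7000,
# 500 < UMI < 50000, percent.mt < 15; 1000 < fragments < per-sample
# mean + 2 SD; nucleosome signal < 2; TSS enrichment > 2), reports the
# per-sample fragment ceilings, and checks how many of the planted
# low-quality nuclei the rules caught.

suppressPackageStartupMessages(library(multilink))

out <- "results/pipeline"
data_dir <- "scratch/pipeline_data"
dataset <- read_multiome_dir(file.path(data_dir, "dataset"))
truth <- jsonlite::read_json(file.path(out, "ground_truth.json"))

qc <- apply_qc(dataset)
utils::write.table(qc$report$metrics, file.path(out, "qc_report.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_multiome_dir(qc$dataset, file.path(data_dir, "dataset_filtered"))

alpha <- qc$report$alpha
message("per-sample ATAC fragment ceilings (mean + 2 SD):")
for (s in names(alpha)) message(sprintf("  %s: %.0f", s, alpha[[s]]))

lowq <- names(truth$is_lowq)[unlist(truth$is_lowq)]
dropped <- qc$report$metrics$cell_id[!qc$report$metrics$keep_joint]
message(sprintf("kept %d / %d cells; planted low-quality sensitivity %.3f",
                nrow(qc$dataset$rna), nrow(dataset$rna),
                mean(lowq %in% dropped)))
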