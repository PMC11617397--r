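#!/usr/bin/env Rscript
# Stage 1: generate the reference synthetic multiome.
#
# 500 nuclei in 3 cell types across 6 samples (2 per condition), 1000
# nuclear genes + 10 mitochondrial pseudo-genes, 20 genes with one planted
# causal peak each (w = 1.5) among 9 in-window and 1 out-of-window decoys,
# plus 5% spiked doublets and 5% low-quality nuclei. Writes the dataset
# directory and the ground truth for the later stages.

suppressPackageStartupMessages(library(multilink))

out <- "results/pipeline"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 13L)
sim <- simulate_dataset(cfg)
data_dir <- "scratch/pipeline_data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
write_multiome_dir(sim$dataset, file.path(data_dir, "dataset"))
jsonlite::write_json(
  list(cell_type = as.list(sim$truth$cell_type),
       is_doublet = as.list(sim$truth$is_doublet),
       is_lowq = as.list(sim$truth$is_lowq),
       markers = sim$truth$markers,
       true_links = sim$truth$true_links),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("simulated %d cells x %d genes / %d peaks; %d planted links, %d doublets, %d low-quality nuclei",
                nrow(sim$dataset$rna), ncol(sim$dataset$rna),
                ncol(sim$dataset$atac), nrow(sim$truth$true_links),
                sum(sim$truth$is_doublet), sum(sim$truth$is_lowq)))
message("wrote ", file.path(data_dir, "dataset"), " (matrices) and ", out, "/ground_truth.json")
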