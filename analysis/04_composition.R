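#!/usr/bin/env Rscript
# Stage 4: cell-type composition testing between conditions.
#
# Tabulates per-sample cell-type counts from the planted labels and fits
# the arcsin-sqrt linear model (condition + region) for each cell type,
# for each disease condition against control. With only 2 samples per
# condition and no planted composition shift, this stage demonstrates the
# contract; calibration and power are established in the test-suite on
# dedicated multinomial simulations.

suppressPackageStartupMessages(library(multilink))

out <- "results/pipeline"
data_dir <- "scratch/pipeline_data"
dataset <- read_multiome_dir(file.path(data_dir, "dataset_filtered"))
truth <- jsonlite::read_json(file.path(out, "ground_truth.json"))

labels <- unlist(truth$cell_type)[dataset$cells$cell_id]
comp <- count_by_sample(labels, dataset$cells)
message("cells per sample x type:")
print(comp$counts)

all_res <- list()
for (cond in c("FCD_IIa", "FCD_IIb")) {
  res <- test_composition(comp, c(cond, "control"))
  if (!is.null(res)) {
    res$contrast <- paste0(cond, "_vs_control")
    all_res[[cond]] <- res
    message(sprintf("%s vs control: min adjusted p = %.3f", cond, min(res$p_adj)))
  }
}
res_all <- do.call(rbind, all_res)
utils::write.table(res_all, file.path(out, "composition.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
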