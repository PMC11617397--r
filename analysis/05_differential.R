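#!/usr/bin/env Rscript
# Stage 5: differential expression and accessibility between cell types.
#
# Wilcoxon rank-sum DE (log2fc gate 0.25, detection gate 10%, BH < 0.05)
# between planted types 1 and 2, and the logistic likelihood-ratio DA
# test with ATAC fragment counts as the latent depth covariate.

suppressPackageStartupMessages(library(multilink))

out <- "results/pipeline"
data_dir <- "scratch/pipeline_data"
dataset <- read_multiome_dir(file.path(data_dir, "dataset_filtered"))
truth <- jsonlite::read_json(file.path(out, "ground_truth.json"))

labels <- unlist(truth$cell_type)[rownames(dataset$rna)]
two <- names(labels)[labels %in% c("type1", "type2")]
sub <- subset_cells(dataset, two)

de <- wilcoxon_de(normalize_log1p(sub$rna), labels[two], group1 = "type1")
utils::write.table(de, file.path(out, "de_type1_vs_type2.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
m1 <- unlist(truth$markers$type1)
message(sprintf("DE: %d genes at BH < 0.05; %d/%d type-1 markers recovered up",
                nrow(de), sum(m1 %in% de$feature_id[de$direction == "up"]),
                length(m1)))

da <- lr_test_da(normalize_log1p(sub$atac), labels[two],
                 latent = stats::setNames(sub$cells$n_fragments,
                                          sub$cells$cell_id),
                 group1 = "type1")
utils::write.table(da, file.path(out, "da_type1_vs_type2.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig_da <- da[da$p_adj < 0.05, ]
message(sprintf("DA: %d peaks tested, %d at BH < 0.05 (%d opening, %d closing in type 1)",
                nrow(da), nrow(sig_da), sum(sig_da$direction == "up"),
                sum(sig_da$direction == "down")))
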