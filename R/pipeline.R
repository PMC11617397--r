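#' Run the full synthetic-multiome demonstration pipeline
#'
#' Executes simulate -> QC -> signature scoring -> composition testing ->
#' differential expression/accessibility -> link inference on the
#' reference synthetic scenario, writes every stage's artifact under
#' `out_dir`, and records a manifest JSON listing each artifact with an
#' md5 checksum. Built-in assertions (planted-link recall, QC sensitivity
#' for planted low-quality nuclei, scoring output in range) determine the
#' returned status.
#'
#' @param config A [sim_config()]; its seed drives every stage through
#'   [derive_seed()].
#' @param out_dir Output directory (created if needed).
#' @param link_parameters A [link_params()]; seed defaults to a derived
#'   stage seed.
#' @return List: `status` (0 on success), `manifest` (data.frame of
#'   artifacts + checksums), `metrics` (named list of the assertion
#'   quantities).
#' @export
run_pipeline <- function(config = sim_config(seed = 13L), out_dir,
                         link_parameters = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)

  # 1. simulate
  sim <- simulate_dataset(config)
  write_multiome_dir(sim$dataset, file.path(out_dir, "dataset"))
  add(file.path(out_dir, "dataset", "cells.tsv"))
  truth_json <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(cell_type = as.list(sim$truth$cell_type),
         is_doublet = as.list(sim$truth$is_doublet),
         is_lowq = as.list(sim$truth$is_lowq),
         true_links = sim$truth$true_links),
    truth_json, auto_unbox = TRUE, digits = NA)
  add(truth_json)

  # 2. qc
  thr <- qc_thresholds()
  qc <- apply_qc(sim$dataset, thr)
  qc_tsv <- file.path(out_dir, "qc_report.tsv")
  utils::write.table(qc$report$metrics, qc_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(qc_tsv)
  lowq <- names(sim$truth$is_lowq)[sim$truth$is_lowq]
  dropped <- qc$report$metrics$cell_id[!qc$report$metrics$keep_joint]
  qc_sensitivity <- if (length(lowq)) mean(lowq %in% dropped) else 1

  # 3. signature scoring on the filtered cells (type1 marker program)
  expr <- normalize_log1p(qc$dataset$rna)
  sig <- sim$truth$markers[[1L]]
  auc <- auc_activity(expr, sig)
  act <- call_active_cells(auc, expr, sig,
                           seed = derive_seed(config$seed, "score"))
  score_tsv <- file.path(out_dir, "signature_scores.tsv")
  utils::write.table(act$cells, score_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(score_tsv)

  # 4. composition (truth labels; conditions from metadata)
  labels <- sim$truth$cell_type[qc$dataset$cells$cell_id]
  comp <- count_by_sample(labels, qc$dataset$cells)
  comp_res <- test_composition(comp, c(config$conditions[2L],
                                       config$conditions[1L]))
  comp_tsv <- file.path(out_dir, "composition.tsv")
  utils::write.table(comp_res, comp_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(comp_tsv)

  # 5. differential expression (type1 vs type2) and accessibility
  two <- names(labels)[labels %in% c("type1", "type2")]
  sub <- subset_cells(qc$dataset, two)
  de <- wilcoxon_de(normalize_log1p(sub$rna), labels[two], group1 = "type1",
                    return_all = TRUE)
  de_tsv <- file.path(out_dir, "de.tsv")
  utils::write.table(de, de_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  add(de_tsv)
  da <- lr_test_da(normalize_log1p(sub$atac), labels[two],
                   latent = stats::setNames(sub$cells$n_fragments,
                                            sub$cells$cell_id),
                   group1 = "type1")
  da_tsv <- file.path(out_dir, "da.tsv")
  utils::write.table(da, da_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  add(da_tsv)

  # 6. links
  if (is.null(link_parameters))
    link_parameters <- link_params(window_bp = config$window_bp,
                                   seed = derive_seed(config$seed, "links"))
  rl <- infer_regulatory_links(qc$dataset, link_parameters)
  links_tsv <- file.path(out_dir, "links.tsv")
  write_links(rl$links, links_tsv, genes = qc$dataset$genes,
              peaks = qc$dataset$peaks)
  add(links_tsv)
  truth_pairs <- paste(sim$truth$true_links$gene_id,
                       sim$truth$true_links$peak_id)
  found_pairs <- paste(rl$links$gene_id, rl$links$peak_id)
  link_recall <- if (length(truth_pairs)) mean(truth_pairs %in% found_pairs) else NA

  metrics <- list(qc_sensitivity = qc_sensitivity,
                  link_recall = link_recall,
                  n_cells_kept = nrow(qc$dataset$rna),
                  active_fraction = mean(act$cells$active))
  ok <- qc_sensitivity >= 0.95 &&
    (is.na(link_recall) || link_recall >= 0.8) &&
    all(act$cells$score >= 0 & act$cells$score <= 1)

  manifest <- data.frame(artifact = basename(artifacts),
                         path = artifacts,
                         md5 = vapply(artifacts, function(f)
                           as.character(tools::md5sum(f)), character(1)))
  manifest_json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(status = if (ok) 0L else 1L,
                            metrics = metrics, artifacts = manifest),
                       manifest_json, auto_unbox = TRUE, digits = NA)
  list(status = if (ok) 0L else 1L, manifest = manifest, metrics = metrics)
}
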