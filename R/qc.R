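#' Cell-level quality-control thresholds
#'
#' All paired bounds are applied as strict (exclusive) inequalities,
#' exactly as printed in the protocols this package emulates: a cell is
#' kept on the RNA side iff `rna_min_features < nFeatures <
#' rna_max_features`, `rna_min_umi < UMI < rna_max_umi`, and `percent.mt <
#' max_percent_mt`; on the ATAC side iff `atac_min_fragments < fragments <
#' alpha` (alpha = per-sample mean + `alpha_sd_multiplier` SD of fragment
#' counts), `nucleosome_signal < max_nucleosome_signal`, and the TSS
#' enrichment rule. The TSS rule direction defaults to `"greater"` (keep
#' cells with enrichment above the threshold), the standard practice;
#' `"less"` is available for bit-faithful reproduction of protocols that
#' print the opposite direction.
#'
#' @param rna_min_features,rna_max_features Exclusive bounds on detected
#'   genes per cell.
#' @param rna_min_umi,rna_max_umi Exclusive bounds on total UMIs per cell.
#' @param max_percent_mt Exclusive upper bound on mitochondrial percentage.
#' @param atac_min_fragments Exclusive lower bound on ATAC fragments.
#' @param alpha_sd_multiplier SD multiplier in the per-sample fragment
#'   ceiling alpha = mean + multiplier * SD.
#' @param alpha_sd_type `"population"` (divide by n; default, deterministic
#'   for single-cell samples) or `"sample"` (n - 1).
#' @param max_nucleosome_signal Exclusive upper bound on nucleosome signal.
#' @param tss_enrichment_threshold TSS enrichment threshold.
#' @param tss_enrichment_direction `"greater"` or `"less"`.
#' @param mito_pattern Regex identifying mitochondrial genes.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(rna_min_features = 400, rna_max_features = 7000,
                          rna_min_umi = 500, rna_max_umi = 50000,
                          max_percent_mt = 15,
                          atac_min_fragments = 1000,
                          alpha_sd_multiplier = 2,
                          alpha_sd_type = c("population", "sample"),
                          max_nucleosome_signal = 2,
                          tss_enrichment_threshold = 2,
                          tss_enrichment_direction = c("greater", "less"),
                          mito_pattern = "^MT-") {
  alpha_sd_type <- match.arg(alpha_sd_type)
  tss_enrichment_direction <- match.arg(tss_enrichment_direction)
  thr <- as.list(environment())
  if (rna_min_features >= rna_max_features || rna_min_umi >= rna_max_umi)
    stop_input("each paired bound needs min < max")
  if (alpha_sd_multiplier <= 0) stop_input("alpha_sd_multiplier must be > 0")
  class(thr) <- "qc_thresholds"
  thr
}

#' Compute per-cell QC metrics for both modalities
#'
#' RNA metrics come from the count matrix: `n_features` (genes with count
#' > 0), `n_umi` (row sum), `percent_mt` (100 x mitochondrial share of
#' UMIs; defined as 0 for all-zero cells). ATAC metrics are consumed from
#' the cell metadata, never recomputed from fragments.
#'
#' @param dataset A `multiome_dataset`.
#' @param mito_pattern Regex identifying mitochondrial genes.
#' @return `data.frame`, one row per cell.
#' @export
compute_cell_metrics <- function(dataset, mito_pattern = "^MT-") {
  rna <- dataset$rna
  if (nrow(rna) == 0L) stop_input("no shared cells between modalities")
  n_umi <- Matrix::rowSums(rna)
  n_features <- Matrix::rowSums(rna > 0)
  mito_cols <- grep(mito_pattern, colnames(rna))
  mt <- if (length(mito_cols)) Matrix::rowSums(rna[, mito_cols, drop = FALSE]) else 0
  percent_mt <- ifelse(n_umi > 0, 100 * mt / n_umi, 0)
  md <- dataset$cells
  data.frame(
    cell_id = rownames(rna),
    sample_id = md$sample_id,
    n_features = as.integer(n_features),
    n_umi = as.integer(n_umi),
    percent_mt = as.numeric(percent_mt),
    n_fragments = md$n_fragments,
    fragments_in_peaks = md$fragments_in_peaks,
    nucleosome_signal = md$nucleosome_signal,
    tss_enrichment = md$tss_enrichment)
}

#' RNA-side cell filter (strict printed bounds)
#'
#' @param metrics From [compute_cell_metrics()].
#' @param thresholds A [qc_thresholds()].
#' @return Logical keep mask, named by cell id.
#' @export
filter_rna_cells <- function(metrics, thresholds = qc_thresholds()) {
  keep <- metrics$n_features > thresholds$rna_min_features &
    metrics$n_features < thresholds$rna_max_features &
    metrics$n_umi > thresholds$rna_min_umi &
    metrics$n_umi < thresholds$rna_max_umi &
    metrics$percent_mt < thresholds$max_percent_mt
  stats::setNames(keep, metrics$cell_id)
}

#' Per-sample ATAC fragment ceilings (alpha = mean + k SD)
#'
#' Computed once over all cells of each sample (single pass, never
#' recomputed on survivors). Samples with fewer than 2 cells get an
#' undefined (infinite) ceiling with a warning, so the upper rule keeps
#' their cells.
#'
#' @param metrics From [compute_cell_metrics()].
#' @param thresholds A [qc_thresholds()].
#' @return Named numeric vector of per-sample alpha values.
#' @export
atac_alpha <- function(metrics, thresholds = qc_thresholds()) {
  pop_sd <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    if (thresholds$alpha_sd_type == "population")
      sqrt(mean((x - mean(x))^2))
    else stats::sd(x)
  }
  samples <- split(metrics$n_fragments, metrics$sample_id)
  alpha <- vapply(samples, function(x) mean(x) + thresholds$alpha_sd_multiplier * pop_sd(x),
                  numeric(1))
  if (anyNA(alpha)) {
    warning("alpha undefined for samples with < 2 cells; fragment ceiling not applied there")
    alpha[is.na(alpha)] <- Inf
  }
  alpha
}

#' ATAC-side cell filter with per-sample adaptive ceiling
#'
#' Keep iff `atac_min_fragments < fragments < alpha(sample)`, nucleosome
#' signal below its cap, and TSS enrichment passes the configured
#' direction. All bounds strict.
#'
#' @param metrics From [compute_cell_metrics()].
#' @param thresholds A [qc_thresholds()].
#' @return List: `keep` (named logical), `alpha` (per-sample ceilings).
#' @export
filter_atac_cells <- function(metrics, thresholds = qc_thresholds()) {
  alpha <- atac_alpha(metrics, thresholds)
  a <- alpha[metrics$sample_id]
  tss_ok <- if (thresholds$tss_enrichment_direction == "greater")
    metrics$tss_enrichment > thresholds$tss_enrichment_threshold
  else
    metrics$tss_enrichment < thresholds$tss_enrichment_threshold
  keep <- metrics$n_fragments > thresholds$atac_min_fragments &
    metrics$n_fragments < a &
    metrics$nucleosome_signal < thresholds$max_nucleosome_signal &
    tss_ok
  list(keep = stats::setNames(keep, metrics$cell_id), alpha = alpha)
}

qc_reason_matrix <- function(metrics, thresholds, alpha) {
  a <- alpha[metrics$sample_id]
  tss_fail <- if (thresholds$tss_enrichment_direction == "greater")
    metrics$tss_enrichment <= thresholds$tss_enrichment_threshold
  else
    metrics$tss_enrichment >= thresholds$tss_enrichment_threshold
  cbind(
    low_features = metrics$n_features <= thresholds$rna_min_features,
    high_features = metrics$n_features >= thresholds$rna_max_features,
    low_umi = metrics$n_umi <= thresholds$rna_min_umi,
    high_umi = metrics$n_umi >= thresholds$rna_max_umi,
    high_mito = metrics$percent_mt >= thresholds$max_percent_mt,
    low_fragments = metrics$n_fragments <= thresholds$atac_min_fragments,
    high_fragments = metrics$n_fragments >= a,
    high_nucleosome = metrics$nucleosome_signal >= thresholds$max_nucleosome_signal,
    tss_enrichment = tss_fail)
}

#' Full QC report: metrics, per-sample alphas, keep flags, drop reasons
#'
#' @param dataset A `multiome_dataset`.
#' @param thresholds A [qc_thresholds()].
#' @return A `qc_report` list: `metrics` (with `keep_rna`, `keep_atac`,
#'   `keep_joint`, and a semicolon-joined `drop_reason` column), `alpha`,
#'   and the thresholds used.
#' @export
qc_report <- function(dataset, thresholds = qc_thresholds()) {
  metrics <- compute_cell_metrics(dataset, thresholds$mito_pattern)
  keep_rna <- filter_rna_cells(metrics, thresholds)
  atac <- filter_atac_cells(metrics, thresholds)
  reasons <- qc_reason_matrix(metrics, thresholds, atac$alpha)
  metrics$keep_rna <- unname(keep_rna)
  metrics$keep_atac <- unname(atac$keep)
  metrics$keep_joint <- metrics$keep_rna & metrics$keep_atac
  metrics$drop_reason <- apply(reasons, 1L, function(r)
    paste(colnames(reasons)[r], collapse = ";"))
  structure(list(metrics = metrics, alpha = atac$alpha,
                 thresholds = thresholds),
            class = "qc_report")
}

#' Apply joint QC to a dataset
#'
#' @param dataset A `multiome_dataset`.
#' @param thresholds A [qc_thresholds()].
#' @return List: `dataset` (kept cells only), `report` (full `qc_report`).
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  report <- qc_report(dataset, thresholds)
  kept <- report$metrics$cell_id[report$metrics$keep_joint]
  list(dataset = subset_cells(dataset, kept), report = report)
}

#' Log-normalize a count matrix (counts per `scale`, log1p)
#'
#' Per cell: `log(1 + count / total * scale)`. All-zero cells map to the
#' zero vector.
#'
#' @param counts Cell-by-feature count matrix.
#' @param scale Size factor target (default 1e4).
#' @return Sparse normalized matrix with the same dimnames.
#' @export
normalize_log1p <- function(counts, scale = 1e4) {
  tot <- Matrix::rowSums(counts)
  fac <- ifelse(tot > 0, scale / tot, 0)
  out <- methods::as(counts, "CsparseMatrix")
  # dgCMatrix stores column-major; recover row index per nonzero entry
  if (length(out@x)) {
    row_of <- out@i + 1L
    out@x <- log1p(out@x * fac[row_of])
  }
  attr(out, "modality") <- attr(counts, "modality")
  out
}
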