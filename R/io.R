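#' Read a 10x-style Matrix Market directory as a cell-by-feature matrix
#'
#' Expects `matrix.mtx`, a features sidecar (`features.tsv`, `genes.tsv` or
#' `peaks.tsv`) and `barcodes.tsv` in `path`. The on-disk 10x convention is
#' features x barcodes; the returned matrix is always oriented cells x
#' features regardless of disk orientation (orientation is resolved from the
#' sidecar lengths). Feature sidecars may carry one column (ids only) or the
#' 10x three-column dialect; extra columns are ignored.
#'
#' @param path Directory containing the three files.
#' @param modality `"rna"` or `"atac"`.
#' @return A count matrix as from [count_matrix()].
#' @export
read_mtx_dir <- function(path, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  mtx_file <- file.path(path, "matrix.mtx")
  bc_file <- file.path(path, "barcodes.tsv")
  feat_file <- Filter(file.exists,
                      file.path(path, c("features.tsv", "genes.tsv", "peaks.tsv")))
  if (!file.exists(mtx_file)) stop_input("missing matrix.mtx in %s", path)
  if (!file.exists(bc_file)) stop_input("missing barcodes.tsv in %s", path)
  if (length(feat_file) == 0L) stop_input("missing features sidecar in %s", path)
  m <- Matrix::readMM(mtx_file)
  feats <- utils::read.table(feat_file[[1L]], sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")[[1L]]
  barcodes <- utils::read.table(bc_file, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")[[1L]]
  if (nrow(m) == length(feats) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                 # disk was features x barcodes
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(feats))) {
    stop_input("matrix dimensions (%d x %d) do not match sidecars (%d features, %d barcodes)",
               nrow(m), ncol(m), length(feats), length(barcodes))
  }
  dimnames(m) <- list(barcodes, feats)
  mat <- try(count_matrix(m, modality), silent = TRUE)
  if (inherits(mat, "try-error"))
    stop_input("invalid matrix in %s: %s", path, attr(mat, "condition")$message)
  mat
}

#' Write a cell-by-feature matrix as a 10x-style Matrix Market directory
#'
#' Writes `matrix.mtx` in the on-disk features x barcodes orientation plus
#' `features.tsv` and `barcodes.tsv`.
#'
#' @param mat Count matrix from [count_matrix()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_mtx_dir <- function(mat, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(mat), file.path(path, "matrix.mtx"))
  writeLines(colnames(mat), file.path(path, "features.tsv"))
  writeLines(rownames(mat), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read BED intervals (0-based half-open) as a peak annotation table
#'
#' @param path BED3+ file; a 4th column, when present, supplies ids,
#'   otherwise ids are synthesized as `chrom:start-end`.
#' @return `data.frame` with `peak_id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_input("no such BED file: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", fill = TRUE)
  if (ncol(raw) < 3L) stop_input("BED needs at least 3 columns")
  start <- as.numeric(raw[[2L]]); end <- as.numeric(raw[[3L]])
  if (anyNA(start) || anyNA(end)) stop_input("non-numeric BED coordinates")
  if (any(start < 0)) stop_input("negative BED start")
  if (any(start >= end)) stop_input("BED requires start < end (0-based half-open)")
  fallback <- sprintf("%s:%d-%d", raw[[1L]], as.integer(start), as.integer(end))
  id <- if (ncol(raw) >= 4L) ifelse(is.na(raw[[4L]]) | !nzchar(raw[[4L]]),
                                    fallback, raw[[4L]])
        else fallback
  data.frame(peak_id = id, chrom = raw[[1L]],
             start = as.integer(start), end = as.integer(end))
}

#' Write peak intervals as BED4
#' @param peaks Peak annotation `data.frame`.
#' @param path Output file.
#' @export
write_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "peak_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation TSV (gene_id, chrom, tss, strand)
#'
#' The TSS is the strand-aware 5' end, given explicitly as a 0-based
#' position; the package never derives it from a gene body interval.
#'
#' @param path TSV with a header row.
#' @return Validated `data.frame`.
#' @export
read_gene_annotation <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character",
                                        "numeric", "character"))
  validate_gene_annotation(g)
}

validate_gene_annotation <- function(g) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(g))) stop_input("gene annotation needs columns %s",
                                           paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop_input("duplicate gene_id")
  if (any(g$tss < 0)) stop_input("tss must be >= 0")
  if (!all(g$strand %in% c("+", "-"))) stop_input("strand must be + or -")
  g$tss <- as.integer(round(g$tss))
  g
}

#' Read per-cell metadata TSV
#' @param path TSV with a header; needs at least `cell_id`, `sample_id`,
#'   `condition`, `n_fragments`, `fragments_in_peaks`, `nucleosome_signal`,
#'   `tss_enrichment`.
#' @return `data.frame`, one row per cell.
#' @export
read_cell_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id", "condition", "n_fragments",
            "fragments_in_peaks", "nucleosome_signal", "tss_enrichment")
  if (!all(need %in% names(md)))
    stop_input("cell metadata needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(md$cell_id)) stop_input("duplicate cell_id in metadata")
  if (any(md$n_fragments < md$fragments_in_peaks))
    stop_input("n_fragments must be >= fragments_in_peaks")
  md
}

#' Write per-cell metadata TSV
#' @param cells Cell metadata `data.frame`.
#' @param path Output file.
#' @export
write_cell_metadata <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

link_tsv_columns <- c("gene_id", "peak_id", "weight", "percentile_rank",
                      "tss_distance", "enhancer_class", "ccre_overlap")

#' Write regulatory links as TSV plus BEDPE
#'
#' The TSV carries gene, peak, weight, within-gene percentile, signed TSS
#' distance, enhancer class, and cCRE overlap. The BEDPE pairs each peak
#' interval with a 1 bp interval at the gene's TSS. Rows are ordered by
#' gene_id, then descending weight.
#'
#' @param links Link `data.frame` as from [infer_regulatory_links()].
#' @param path Output TSV path; the BEDPE is written next to it with a
#'   `.bedpe` extension.
#' @param genes Gene annotation (for TSS coordinates in the BEDPE).
#' @param peaks Peak annotation (for peak intervals in the BEDPE).
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path, genes = NULL, peaks = NULL) {
  links <- links[order(links$gene_id, -links$weight), , drop = FALSE]
  utils::write.table(links[, link_tsv_columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bedpe_path <- sub("\\.tsv$", "", path)
  bedpe_path <- paste0(bedpe_path, ".bedpe")
  if (!is.null(genes) && !is.null(peaks)) {
    gi <- match(links$gene_id, genes$gene_id)
    pi <- match(links$peak_id, peaks$peak_id)
    bedpe <- data.frame(
      chrom1 = peaks$chrom[pi], start1 = peaks$start[pi], end1 = peaks$end[pi],
      chrom2 = genes$chrom[gi], start2 = genes$tss[gi], end2 = genes$tss[gi] + 1L,
      name = paste(links$peak_id, links$gene_id, sep = "|"),
      score = links$weight)
    utils::write.table(bedpe, bedpe_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bedpe_path)
  }
  invisible(path)
}

#' Read a regulatory link TSV written by [write_links()]
#' @param path TSV path.
#' @return Link `data.frame`.
#' @export
read_links <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(link_tsv_columns %in% names(out)))
    stop_input("not a link table: %s", path)
  out$ccre_overlap <- as.logical(out$ccre_overlap)
  out
}

#' Write a whole multiome dataset to a directory
#'
#' Lays out `rna/` and `atac/` MTX directories, `genes.tsv`, `peaks.bed`,
#' and `cells.tsv`.
#'
#' @param dataset A `multiome_dataset`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_multiome_dir <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_mtx_dir(dataset$rna, file.path(path, "rna"))
  write_mtx_dir(dataset$atac, file.path(path, "atac"))
  utils::write.table(dataset$genes, file.path(path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(dataset$peaks, file.path(path, "peaks.bed"))
  write_cell_metadata(dataset$cells, file.path(path, "cells.tsv"))
  invisible(path)
}

#' Read a multiome dataset directory written by [write_multiome_dir()]
#' @param path Dataset directory.
#' @return A `multiome_dataset`.
#' @export
read_multiome_dir <- function(path) {
  multiome_dataset(
    rna = read_mtx_dir(file.path(path, "rna"), "rna"),
    atac = read_mtx_dir(file.path(path, "atac"), "atac"),
    cells = read_cell_metadata(file.path(path, "cells.tsv")),
    genes = read_gene_annotation(file.path(path, "genes.tsv")),
    peaks = read_bed(file.path(path, "peaks.bed")))
}
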