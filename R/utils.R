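#' Derive a stage-specific seed from a global seed
#'
#' Deterministically fans a single pipeline seed out to named stages so that
#' stages draw from independent streams without seed collisions.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. "simulate", "qc").
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L))
}

# Run code with a local RNG state so package functions never disturb the
# caller's .Random.seed. NULL seed means "use current stream" (still restored).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct a validated cell-by-feature count matrix
#'
#' The package-wide count container: a sparse `dgCMatrix` with cells in
#' rows and features in columns, unique ids on both axes, nonnegative
#' integer entries, and a `modality` attribute.
#'
#' @param counts Matrix-like, cells in rows, features in columns.
#' @param modality `"rna"` or `"atac"`.
#' @return A sparse `dgCMatrix` carrying a `modality` attribute.
#' @export
count_matrix <- function(counts, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  m <- counts
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_input("count_matrix requires cell ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop_input("cell and feature ids must be unique")
  v <- m@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop_input("counts must be nonnegative integers")
  attr(m, "modality") <- modality
  m
}

modality_of <- function(x) attr(x, "modality")

is_count_matrix <- function(x) {
  methods::is(x, "dgCMatrix") && !is.null(attr(x, "modality"))
}

#' Bundle paired RNA and ATAC matrices with their annotations
#'
#' @param rna,atac Count matrices from [count_matrix()] over the same cells,
#'   in the same order.
#' @param cells Per-cell metadata `data.frame` (one row per cell; must
#'   contain `cell_id`, `sample_id`, `condition`, `n_fragments`,
#'   `fragments_in_peaks`, `nucleosome_signal`, `tss_enrichment`).
#' @param genes Gene annotation `data.frame` (`gene_id`, `chrom`, `tss`,
#'   `strand`), TSS as a 0-based position.
#' @param peaks Peak annotation `data.frame` (`peak_id`, `chrom`, `start`,
#'   `end`), 0-based half-open intervals.
#' @return A `multiome_dataset` list.
#' @export
multiome_dataset <- function(rna, atac, cells, genes, peaks) {
  if (!identical(rownames(rna), rownames(atac)))
    stop_input("rna and atac matrices must share identical cell ids in the same order")
  if (!setequal(cells$cell_id, rownames(rna)) ||
      nrow(cells) != nrow(rna))
    stop_input("cell metadata must cover exactly the matrix cells")
  cells <- cells[match(rownames(rna), cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  if (!all(colnames(rna) %in% genes$gene_id))
    stop_input("every RNA feature needs a gene annotation row")
  if (!all(colnames(atac) %in% peaks$peak_id))
    stop_input("every ATAC feature needs a peak annotation row")
  structure(list(rna = rna, atac = atac, cells = cells,
                 genes = genes, peaks = peaks),
            class = "multiome_dataset")
}

#' @export
print.multiome_dataset <- function(x, ...) {
  cat(sprintf("multiome_dataset: %d cells, %d genes, %d peaks, %d samples\n",
              nrow(x$rna), ncol(x$rna), ncol(x$atac),
              length(unique(x$cells$sample_id))))
  invisible(x)
}

#' Subset a multiome dataset to a set of cells
#'
#' @param dataset A `multiome_dataset`.
#' @param cell_ids Character vector of cell ids; output preserves this order.
#' @return A `multiome_dataset` over the requested cells.
#' @export
subset_cells <- function(dataset, cell_ids) {
  idx <- match(cell_ids, rownames(dataset$rna))
  if (anyNA(idx)) stop_input("unknown cell ids in subset")
  rna <- dataset$rna[idx, , drop = FALSE]
  atac <- dataset$atac[idx, , drop = FALSE]
  attr(rna, "modality") <- "rna"
  attr(atac, "modality") <- "atac"
  multiome_dataset(rna, atac,
                   dataset$cells[match(cell_ids, dataset$cells$cell_id), , drop = FALSE],
                   dataset$genes, dataset$peaks)
}
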