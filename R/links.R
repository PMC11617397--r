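#' Parameters for cis-regulatory link inference
#'
#' @param window_bp Total window span centered on the TSS (bp; the
#'   candidate window is `[TSS - window_bp/2, TSS + window_bp/2)`).
#' @param n_trees Random-forest trees per gene.
#' @param select_percentile Per-gene weight percentile above which peaks
#'   are selected (ties at the threshold included).
#' @param min_candidates Genes with fewer candidate peaks are skipped (a
#'   high percentile over 2-3 weights is degenerate).
#' @param seed Integer seed; per-gene forests draw deterministic derived
#'   seeds.
#' @return A `link_params` list.
#' @export
link_params <- function(window_bp = 500000, n_trees = 200,
                        select_percentile = 95, min_candidates = 5L,
                        seed = 1L) {
  stopifnot(window_bp > 0, n_trees >= 1,
            select_percentile > 0, select_percentile < 100,
            min_candidates >= 2)
  structure(list(window_bp = window_bp, n_trees = n_trees,
                 select_percentile = select_percentile,
                 min_candidates = as.integer(min_candidates),
                 seed = as.integer(seed)),
            class = "link_params")
}

#' Candidate peaks in the window around a gene's TSS
#'
#' A peak is a candidate iff its (0-based half-open) interval intersects
#' `[TSS - window_bp/2, TSS + window_bp/2)`. The signed distance runs from
#' the TSS to the nearest peak edge (0 when the peak covers the TSS) and
#' is oriented by strand: positive downstream of the gene.
#'
#' @param gene One-row gene annotation (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param peaks Peak annotation `data.frame`.
#' @param params A [link_params()].
#' @return `data.frame`: `peak_id`, `tss_distance`.
#' @export
candidate_peaks <- function(gene, peaks, params = link_params()) {
  w2 <- params$window_bp / 2
  lo <- gene$tss - w2
  hi <- gene$tss + w2
  same <- peaks$chrom == gene$chrom
  p <- peaks[same, , drop = FALSE]
  if (nrow(p) == 0L)
    return(data.frame(peak_id = character(0), tss_distance = integer(0)))
  # half-open vs half-open overlap via IRanges (1-based closed conversion)
  q <- IRanges::IRanges(start = p$start + 1L, end = p$end)
  win <- IRanges::IRanges(start = lo + 1L, end = hi)
  hit <- IRanges::overlapsAny(q, win)
  p <- p[hit, , drop = FALSE]
  d <- ifelse(p$start > gene$tss, p$start - gene$tss,
              ifelse(p$end <= gene$tss, p$end - gene$tss, 0L))
  if (gene$strand == "-") d <- -d
  data.frame(peak_id = p$peak_id, tss_distance = as.integer(d))
}

#' Random-forest peak weights for one gene
#'
#' Regression of a gene's per-cell expression on the accessibility of its
#' candidate peaks; the weight of a peak is its total impurity-reduction
#' importance, clipped at zero and normalized to sum to 1 across the
#' gene's candidates (so percentile selection is scale-free).
#' Deterministic given the seed (single-threaded forest).
#'
#' @param x_g Numeric per-cell expression of the gene.
#' @param A Cell-by-candidate-peak accessibility matrix (>= 2 columns).
#' @param params A [link_params()].
#' @param seed Seed for this gene's forest (defaults to `params$seed`).
#' @return Named weight vector summing to 1, or all-zero with attribute
#'   `untestable = TRUE` when the gene's expression is constant.
#' @export
fit_gene_links_rf <- function(x_g, A, params = link_params(), seed = NULL) {
  A <- as.matrix(A)
  if (ncol(A) < 2L) stop_input("need >= 2 candidate peaks")
  zero <- stats::setNames(rep(0, ncol(A)), colnames(A))
  if (stats::sd(x_g) == 0) {
    attr(zero, "untestable") <- TRUE
    return(zero)
  }
  df <- data.frame(A, check.names = FALSE)
  fit <- ranger::ranger(
    x = df, y = x_g,
    num.trees = params$n_trees,
    mtry = max(1L, floor(sqrt(ncol(A)))),
    importance = "impurity",
    num.threads = 1L,
    seed = if (is.null(seed)) params$seed else seed)
  imp <- pmax(fit$variable.importance, 0)
  if (sum(imp) == 0) return(zero)
  imp[colnames(A)] / sum(imp)
}

#' Least-squares peak weights for one gene (linear cross-check)
#'
#' Ordinary least squares of expression on candidate-peak accessibility
#' (with intercept); used as an independent linear oracle for the
#' random-forest ranking, never for selection. Rank-deficient designs get
#' a minimal ridge and are flagged.
#'
#' @param x_g Numeric per-cell expression.
#' @param A Cell-by-candidate-peak accessibility matrix.
#' @return Named coefficient vector (no intercept term); attribute
#'   `ridged = TRUE` when regularization was needed.
#' @export
fit_gene_links_linear <- function(x_g, A) {
  A <- as.matrix(A)
  X <- cbind(`(Intercept)` = 1, A)
  qr_X <- qr(X)
  if (qr_X$rank == ncol(X)) {
    w <- qr.coef(qr_X, x_g)[-1L]
    return(stats::setNames(as.numeric(w), colnames(A)))
  }
  lambda <- 1e-6 * mean(diag(crossprod(X)))
  w <- solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, x_g))[-1L]
  out <- stats::setNames(as.numeric(w), colnames(A))
  attr(out, "ridged") <- TRUE
  out
}

#' Select top-percentile peaks per gene
#'
#' The percentile threshold is computed per gene over that gene's own
#' candidate weights; peaks with weight greater than or equal to the
#' threshold are selected, so ties at the threshold are all included.
#'
#' @param weights Named numeric weight vector for one gene's candidates.
#' @param params A [link_params()].
#' @return Names of the selected peaks.
#' @export
select_top_links <- function(weights, params = link_params()) {
  thr <- stats::quantile(weights, params$select_percentile / 100,
                         names = FALSE, type = 7)
  names(weights)[weights >= thr]
}

#' Classify a peak by signed TSS distance into enhancer-like classes
#'
#' `|d| = 0` means the peak covers the TSS (`TSS_overlap`); distances up
#' to 200 bp are promoter-proximal and not enhancer-like (`none`);
#' `200 < |d| <= 2000` is proximal enhancer-like (`pELS`, inclusive 2 kb
#' ceiling); `|d| > 2000` is distal enhancer-like (`dELS`).
#'
#' @param tss_distance Signed distance(s) in bp.
#' @return Character vector of classes.
#' @export
classify_enhancer_distance <- function(tss_distance) {
  d <- abs(tss_distance)
  ifelse(d == 0, "TSS_overlap",
         ifelse(d <= 200, "none",
                ifelse(d <= 2000, "pELS", "dELS")))
}

#' Flag links whose peak overlaps any cCRE interval
#'
#' Overlap is a nonempty intersection under half-open semantics; touching
#' intervals (peak end equal to cCRE start) do not overlap. Chromosome
#' names are matched literally; a mismatch in naming style (e.g. "1" vs
#' "chr1") yields a warning with a harmonization hint.
#'
#' @param links Link `data.frame` with a `peak_id` column.
#' @param peaks Peak annotation covering the link peaks.
#' @param ccre cCRE intervals as a peak-annotation `data.frame` (e.g. from
#'   [read_bed()]).
#' @return `links` with a logical `ccre_overlap` column.
#' @export
annotate_ccre_overlap <- function(links, peaks, ccre) {
  if (nrow(links) == 0L) {
    links$ccre_overlap <- logical(0)
    return(links)
  }
  pi <- match(links$peak_id, peaks$peak_id)
  if (anyNA(pi)) stop_input("link peak missing from peak annotation")
  if (nrow(ccre) && !any(ccre$chrom %in% peaks$chrom[pi]))
    warning("no shared chromosome names between peaks and cCREs; harmonize naming (e.g. 'chr1' vs '1')")
  gr_peaks <- GenomicRanges::GRanges(
    peaks$chrom[pi],
    IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi]))
  gr_ccre <- GenomicRanges::GRanges(
    ccre$chrom, IRanges::IRanges(start = ccre$start + 1L, end = ccre$end))
  links$ccre_overlap <- IRanges::overlapsAny(gr_peaks, gr_ccre)
  links
}

#' Infer cis-regulatory peak-to-gene links on a QC-filtered dataset
#'
#' Accessibility is depth-normalized (counts over per-cell total counts in
#' peaks, x 1e4, log1p); expression is log-normalized. For every gene on
#' an annotated chromosome with at least `min_candidates` candidate peaks
#' in its window, a random forest ranks the candidates, the top
#' `select_percentile` weights are selected (ties included), distances
#' are classified into enhancer-like classes, and cCRE overlap is
#' annotated when a registry is supplied. Cells are canonically ordered by
#' cell id before fitting, so jointly permuting the cell order of both
#' matrices leaves the output identical; per-gene forest seeds derive from
#' `params$seed` and the gene id.
#'
#' @param dataset A QC-filtered `multiome_dataset`.
#' @param params A [link_params()].
#' @param ccre Optional cCRE `data.frame` (chrom/start/end) for overlap
#'   annotation.
#' @param genes,peaks Optional annotation overrides (default from
#'   `dataset`).
#' @return A `regulatory_links` object: `links` `data.frame` (`gene_id`,
#'   `peak_id`, `weight`, `percentile_rank`, `tss_distance`,
#'   `enhancer_class`, `ccre_overlap`), plus `gene_info` (per-gene
#'   candidate counts and skip/untestable flags) and the `params` used.
#' @export
infer_regulatory_links <- function(dataset, params = link_params(),
                                   ccre = NULL, genes = NULL, peaks = NULL) {
  genes <- if (is.null(genes)) dataset$genes else genes
  peaks <- if (is.null(peaks)) dataset$peaks else peaks
  ord <- order(rownames(dataset$rna))
  expr <- normalize_log1p(dataset$rna[ord, , drop = FALSE])
  acc_counts <- dataset$atac[ord, , drop = FALSE]
  acc <- normalize_log1p(acc_counts)        # denominator = counts in peaks
  acc <- as.matrix(acc)

  gene_rows <- genes[genes$gene_id %in% colnames(expr), , drop = FALSE]
  links <- list()
  info <- list()
  for (g in seq_len(nrow(gene_rows))) {
    gene <- gene_rows[g, , drop = FALSE]
    cand <- candidate_peaks(gene, peaks, params)
    status <- "ok"
    if (nrow(cand) < params$min_candidates) {
      status <- "too_few_candidates"
    } else {
      x_g <- as.numeric(expr[, gene$gene_id])
      w <- fit_gene_links_rf(x_g, acc[, cand$peak_id, drop = FALSE], params,
                             seed = derive_seed(params$seed, gene$gene_id))
      if (isTRUE(attr(w, "untestable"))) {
        status <- "constant_expression"
      } else {
        sel <- select_top_links(w, params)
        pr <- 100 * vapply(w, function(wi) mean(w <= wi), numeric(1))
        ki <- match(sel, cand$peak_id)
        links[[gene$gene_id]] <- data.frame(
          gene_id = gene$gene_id,
          peak_id = sel,
          weight = as.numeric(w[sel]),
          percentile_rank = as.numeric(pr[sel]),
          tss_distance = cand$tss_distance[ki])
      }
    }
    info[[gene$gene_id]] <- data.frame(
      gene_id = gene$gene_id, n_candidates = nrow(cand), status = status)
  }
  out <- if (length(links)) do.call(rbind, links) else
    data.frame(gene_id = character(0), peak_id = character(0),
               weight = numeric(0), percentile_rank = numeric(0),
               tss_distance = integer(0))
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no genes testable; empty link set")
  out$enhancer_class <- classify_enhancer_distance(out$tss_distance)
  out <- if (!is.null(ccre)) annotate_ccre_overlap(out, peaks, ccre)
         else { out$ccre_overlap <- rep(NA, nrow(out)); out }
  structure(list(links = out,
                 gene_info = do.call(rbind, c(info, make.row.names = FALSE)),
                 params = params),
            class = "regulatory_links")
}

#' @export
print.regulatory_links <- function(x, ...) {
  cat(sprintf("regulatory_links: %d links over %d genes (%d genes profiled)\n",
              nrow(x$links), length(unique(x$links$gene_id)),
              nrow(x$gene_info)))
  invisible(x)
}
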