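#' Bin genes by average expression
#'
#' Equal-frequency bins of the per-gene mean (over cells) of the
#' normalized expression matrix; ties broken by stable feature order.
#' Shared by the module score (control-gene matching) and the
#' null-calibrated activity threshold.
#'
#' @param norm_expr Cell-by-gene normalized matrix.
#' @param n_bins Number of bins.
#' @return Integer bin index named by gene.
#' @export
expression_bins <- function(norm_expr, n_bins = 25) {
  avg <- Matrix::colMeans(norm_expr)
  n_bins <- min(n_bins, length(avg))
  r <- rank(avg, ties.method = "first")
  bins <- as.integer(ceiling(r / length(avg) * n_bins))
  stats::setNames(bins, colnames(norm_expr))
}

harmonize_signature <- function(signature, universe) {
  sig <- unique(signature)
  missing <- setdiff(sig, universe)
  if (length(missing))
    warning(sprintf("%d signature gene(s) absent from the matrix, dropped",
                    length(missing)))
  sig <- intersect(sig, universe)
  if (length(sig) == 0L) stop_input("signature empty after harmonization")
  sig
}

#' Bin-matched module score
#'
#' For each signature gene, `n_ctrl` control genes are sampled from the
#' same average-expression bin (without replacement when the bin is large
#' enough, with replacement otherwise). The per-cell score is the mean
#' expression over signature genes minus the mean over the pooled control
#' draw (a multiset; duplicates count). A global additive shift of the
#' matrix therefore cancels exactly.
#'
#' @param norm_expr Cell-by-gene normalized matrix.
#' @param signature Character vector of gene ids.
#' @param n_bins Expression bins for control matching.
#' @param n_ctrl Control genes sampled per signature gene.
#' @param seed Integer seed (control sampling is the only randomness).
#' @return Named numeric score per cell.
#' @export
module_score <- function(norm_expr, signature, n_bins = 25, n_ctrl = 100,
                         seed = 1L) {
  sig <- harmonize_signature(signature, colnames(norm_expr))
  bins <- expression_bins(norm_expr, n_bins)
  ctrl <- with_seed(seed, {
    unlist(lapply(sig, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
      else sample(pool, n_ctrl, replace = TRUE)
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::rowMeans(norm_expr[, sig, drop = FALSE])
  # pooled control multiset: duplicates contribute repeatedly to the mean
  ctrl_tab <- table(ctrl)
  ctrl_mat <- norm_expr[, names(ctrl_tab), drop = FALSE]
  ctrl_mean <- as.numeric(ctrl_mat %*% as.numeric(ctrl_tab)) / length(ctrl)
  stats::setNames(as.numeric(sig_mean - ctrl_mean), rownames(norm_expr))
}

#' Ranking-based gene-set activity (AUC of the recovery curve)
#'
#' Per cell, genes are ranked by decreasing expression (ties broken by
#' stable feature order) and the recovery curve counts signature genes
#' among the top `ceiling(top_frac * n_genes)` ranks; the area under that
#' step curve is normalized by its maximum attainable value, so scores lie
#' in `[0, 1]`, reaching 1 when the signature occupies the very top ranks
#' and 0 when no signature gene enters the top fraction. Invariant under
#' any per-cell strictly monotone transform of expression.
#'
#' @param norm_expr Cell-by-gene normalized matrix.
#' @param signature Character vector of gene ids.
#' @param top_frac Fraction of the ranking integrated (default 0.05).
#' @return Named numeric AUC per cell.
#' @export
auc_activity <- function(norm_expr, signature, top_frac = 0.05) {
  sig <- harmonize_signature(signature, colnames(norm_expr))
  n_genes <- ncol(norm_expr)
  if (top_frac * n_genes < 1)
    stop_input("top_frac * n_genes must be >= 1")
  k <- as.integer(ceiling(top_frac * n_genes))
  rk <- rank_matrix(norm_expr)
  auc_from_ranks(rk, match(sig, colnames(norm_expr)), k)
}

# per-cell descending ranks, ties broken by stable feature order
rank_matrix <- function(norm_expr) {
  dense <- as.matrix(norm_expr)
  t(apply(dense, 1L, function(x) rank(-x, ties.method = "first")))
}

auc_from_ranks <- function(rk, sig_idx, k) {
  s <- length(sig_idx)
  max_area <- if (s <= k) s * (s + 1) / 2 + (k - s) * s else k * (k + 1) / 2
  r <- rk[, sig_idx, drop = FALSE]
  contrib <- pmax(k - r + 1, 0)   # first arg keeps matrix dims
  stats::setNames(rowSums(contrib) / max_area, rownames(rk))
}

#' Call signature-active cells against a bin-matched null
#'
#' The null pools AUC scores of `n_null` random gene sets drawn
#' bin-matched to the signature (one draw from each signature gene's
#' average-expression bin per set). The activity threshold is the
#' `q`-quantile of the pooled null scores; cells strictly above it are
#' called active.
#'
#' @param scores AUC scores from [auc_activity()] for the real signature.
#' @param norm_expr Cell-by-gene normalized matrix (for the null draws).
#' @param signature The signature the scores belong to.
#' @param n_null Number of null gene sets (must be >= 1).
#' @param q Null quantile used as threshold.
#' @param seed Integer seed.
#' @param top_frac Passed through to [auc_activity()].
#' @param n_bins Expression bins for the matched null.
#' @return An `activity_result` list: `cells` (`cell_id`, `score`,
#'   `active`), `threshold`, `method = "auc"`.
#' @export
call_active_cells <- function(scores, norm_expr, signature, n_null = 100,
                              q = 0.99, seed = 1L, top_frac = 0.05,
                              n_bins = 25) {
  if (n_null < 1) stop_input("n_null must be >= 1")
  sig <- harmonize_signature(signature, colnames(norm_expr))
  bins <- expression_bins(norm_expr, n_bins)
  sig_bins <- bins[sig]
  by_bin <- split(names(bins), bins)
  n_genes <- ncol(norm_expr)
  if (top_frac * n_genes < 1) stop_input("top_frac * n_genes must be >= 1")
  k <- as.integer(ceiling(top_frac * n_genes))
  rk <- rank_matrix(norm_expr)
  null_scores <- with_seed(seed, {
    unlist(lapply(seq_len(n_null), function(j) {
      null_set <- unique(vapply(sig_bins, function(b) {
        pool <- by_bin[[as.character(b)]]
        pool[sample.int(length(pool), 1L)]
      }, character(1)))
      auc_from_ranks(rk, match(null_set, colnames(norm_expr)), k)
    }), use.names = FALSE)
  })
  threshold <- as.numeric(stats::quantile(null_scores, q))
  cells <- data.frame(cell_id = names(scores),
                      score = as.numeric(scores),
                      active = as.numeric(scores) > threshold)
  structure(list(cells = cells, threshold = threshold, method = "auc"),
            class = "activity_result")
}
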