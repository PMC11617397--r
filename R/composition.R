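#' Tabulate cell-type counts per sample
#'
#' @param labels Per-cell type labels, named by cell id (or in the order of
#'   `metadata`).
#' @param metadata Cell metadata with `cell_id`, `sample_id`, `condition`,
#'   and (optionally) `region`.
#' @return A `composition_table` list: `counts` (samples x cell types,
#'   zero-count types retained), `sample_info` (`sample_id`, `condition`,
#'   `region`).
#' @export
count_by_sample <- function(labels, metadata) {
  if (length(labels) == 0L) stop_input("empty label vector")
  if (!is.null(names(labels))) {
    idx <- match(names(labels), metadata$cell_id)
    if (anyNA(idx)) stop_input("unknown cell id in labels")
    metadata <- metadata[idx, , drop = FALSE]
  } else if (length(labels) != nrow(metadata)) {
    stop_input("unnamed labels must match metadata rows")
  }
  if (!all(metadata$sample_id %in% unique(metadata$sample_id)))
    stop_input("unknown sample id")
  counts <- table(sample_id = metadata$sample_id, cell_type = labels)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  info <- unique(metadata[, intersect(c("sample_id", "condition", "region"),
                                      names(metadata)), drop = FALSE])
  if (anyDuplicated(info$sample_id))
    stop_input("inconsistent condition/region within a sample")
  if (is.null(info$region)) info$region <- "all"
  rownames(info) <- NULL
  structure(list(counts = counts,
                 sample_info = info[match(rownames(counts), info$sample_id), ]),
            class = "composition_table")
}

transform_proportions <- function(p, transform) {
  switch(transform,
         arcsin = asin(sqrt(p)),
         logit = qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)),
         stop_input("unknown transform '%s'", transform))
}

#' Test cell-type composition differences between two conditions
#'
#' Per-sample cell-type proportions are variance-stabilized (arcsin square
#' root by default) and each cell type is fit by ordinary least squares on
#' condition (treatment-coded, reference level second in `contrast`) plus
#' region. The condition coefficient gets a two-sided t test;
#' Benjamini-Hochberg adjustment is applied across cell types within the
#' contrast. If region is collinear with condition (or constant) it is
#' dropped with a message.
#'
#' @param comp A `composition_table` from [count_by_sample()].
#' @param contrast Character length-2: `c(group, reference)`.
#' @param transform `"arcsin"` (default) or `"logit"`.
#' @return `data.frame`: `cell_type`, `prop_group`, `prop_ref`, `estimate`
#'   (transformed scale), `t`, `df`, `p`, `p_adj`.
#' @export
test_composition <- function(comp, contrast, transform = c("arcsin", "logit")) {
  transform <- match.arg(transform)
  stopifnot(inherits(comp, "composition_table"), length(contrast) == 2L)
  info <- comp$sample_info
  keep <- info$condition %in% contrast
  info <- info[keep, , drop = FALSE]
  counts <- comp$counts[keep, , drop = FALSE]
  n_per <- table(factor(info$condition, levels = contrast))
  if (any(n_per < 2L)) {
    warning(sprintf("contrast %s vs %s skipped: a condition has < 2 samples",
                    contrast[1L], contrast[2L]))
    return(NULL)
  }
  rs <- rowSums(counts)
  if (any(rs == 0)) stop_input("sample with zero cells")
  props <- counts / rs
  y <- transform_proportions(props, transform)

  cond <- factor(info$condition, levels = c(contrast[2L], contrast[1L]))
  region <- factor(info$region)
  X <- stats::model.matrix(~cond)
  if (nlevels(region) > 1L) {
    X_full <- stats::model.matrix(~ cond + region)
    if (qr(X_full)$rank == ncol(X_full)) X <- X_full
    else message("region collinear with condition; dropped from the model")
  }
  p_par <- ncol(X)
  n <- nrow(X)
  if (n <= p_par) stop_input("not enough samples for the model")
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, y)
  res <- y - X %*% beta
  df_res <- n - p_par
  sigma2 <- colSums(res^2) / df_res
  j <- 2L  # condition coefficient (treatment coding, reference = contrast[2])
  se <- sqrt(sigma2 * XtX_inv[j, j])
  tval <- ifelse(se > 0, beta[j, ] / se, 0)
  pval <- ifelse(se > 0, 2 * stats::pt(-abs(tval), df_res), 1)
  out <- data.frame(
    cell_type = colnames(counts),
    prop_group = colMeans(props[info$condition == contrast[1L], , drop = FALSE]),
    prop_ref = colMeans(props[info$condition == contrast[2L], , drop = FALSE]),
    estimate = as.numeric(beta[j, ]),
    t = as.numeric(tval),
    df = df_res,
    p = as.numeric(pval))
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
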