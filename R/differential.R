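#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around the standard step-up procedure; inputs
#' outside `[0, 1]` are rejected rather than propagated.
#'
#' @param p Numeric vector of p values.
#' @return Adjusted p values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_input("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Two-sided rank-sum p value for values v split by logical g1.
# Exact enumeration over group assignments when feasible (handles ties by
# construction), tie-corrected normal approximation otherwise (no
# continuity correction).
rank_sum_test <- function(v, g1, exact_max = 5000) {
  n <- length(v)
  n1 <- sum(g1)
  r <- rank(v)                       # midranks
  W <- sum(r[g1])
  if (choose(n, n1) <= exact_max) {
    combs <- utils::combn(n, n1)
    dist <- colSums(matrix(r[combs], nrow = n1))
    p <- min(1, 2 * min(mean(dist <= W + 1e-9), mean(dist >= W - 1e-9)))
    return(list(statistic = W, p = p, method = "exact"))
  }
  n2 <- n - n1
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = W, p = 1, method = "normal"))
  z <- (W - mu) / sqrt(sigma2)
  list(statistic = W, p = 2 * stats::pnorm(-abs(z)), method = "normal")
}

de_fold_change <- function(x1, x2) {
  log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))
}

split_two_groups <- function(group_labels, cell_ids, group1) {
  if (!is.null(names(group_labels)))
    group_labels <- group_labels[cell_ids]
  lv <- unique(as.character(group_labels))
  if (length(lv) != 2L) stop_input("exactly two groups required")
  if (is.null(group1)) group1 <- lv[1L]
  if (!group1 %in% lv) stop_input("group1 '%s' not found", group1)
  g1 <- as.character(group_labels) == group1
  if (sum(g1) == 0L || sum(!g1) == 0L) stop_input("a group is empty")
  list(g1 = g1, group1 = group1, group2 = setdiff(lv, group1))
}

#' Rank-sum differential expression with detection and fold-change gates
#'
#' Genes are tested iff detected (expression > 0) in at least `min_pct` of
#' cells in the more-detected group; every tested gene gets a two-sided
#' rank-sum test (exact enumeration for tiny groups, tie-corrected normal
#' approximation otherwise) and BH adjustment across all tested genes.
#' Genes with `|log2fc| < logfc_threshold` are then excluded from the
#' output, where `log2fc = log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) +
#' 1))` on the log-normalized matrix; adjusting before the fold-change
#' exclusion keeps the multiplicity correction unbiased by that filter.
#'
#' @param norm_expr Cell-by-gene log-normalized matrix.
#' @param group_labels Two-level vector over cells (named by cell id or in
#'   matrix order).
#' @param group1 Which level is "group 1" (log2fc > 0 means higher there);
#'   defaults to the first level encountered.
#' @param logfc_threshold Absolute log2 fold-change gate (default 0.25).
#' @param min_pct Detection-fraction gate (default 0.10).
#' @param p_adj_max Keep only genes with adjusted p below this (default
#'   0.05); set `return_all = TRUE` to keep every tested gene.
#' @param return_all Return all tested genes regardless of adjusted p.
#' @return `data.frame`: `feature_id`, `log2fc`, `pct_group1`,
#'   `pct_group2`, `statistic`, `p`, `p_adj`, `direction`.
#' @export
wilcoxon_de <- function(norm_expr, group_labels, group1 = NULL,
                        logfc_threshold = 0.25, min_pct = 0.10,
                        p_adj_max = 0.05, return_all = FALSE) {
  grp <- split_two_groups(group_labels, rownames(norm_expr), group1)
  g1 <- grp$g1
  if (sum(g1) < 3L || sum(!g1) < 3L)
    stop_input("each group needs >= 3 cells")
  x <- as.matrix(norm_expr)
  pct1 <- colMeans(x[g1, , drop = FALSE] > 0)
  pct2 <- colMeans(x[!g1, , drop = FALSE] > 0)
  # "tested" is defined by the detection gate alone; BH spans all tested
  # genes so the fold-change rule acts as an output filter, not a
  # selection step that would bias the adjustment
  idx <- which(pmax(pct1, pct2) >= min_pct)
  if (length(idx) == 0L)
    return(empty_stat_table())
  fc <- vapply(idx, function(j) de_fold_change(x[g1, j], x[!g1, j]),
               numeric(1))
  res <- lapply(idx, function(j) rank_sum_test(x[, j], g1))
  out <- data.frame(
    feature_id = colnames(x)[idx],
    log2fc = fc,
    pct_group1 = pct1[idx],
    pct_group2 = pct2[idx],
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p = vapply(res, `[[`, numeric(1), "p"))
  out$p_adj <- bh_adjust(out$p)
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out <- out[abs(out$log2fc) >= logfc_threshold, , drop = FALSE]
  if (!return_all) out <- out[out$p_adj < p_adj_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_stat_table <- function() {
  data.frame(feature_id = character(0), log2fc = numeric(0),
             pct_group1 = numeric(0), pct_group2 = numeric(0),
             statistic = numeric(0), p = numeric(0), p_adj = numeric(0),
             direction = character(0))
}

# Penalized (ridge) logistic log-likelihood fit by IRLS; fallback for
# separated fits. Returns unpenalized log-likelihood at the ridge solution.
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1L, 1L] <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  mu <- stats::plogis(drop(X %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

logistic_lrt <- function(feature, y, log_latent) {
  X_full <- cbind(1, feature, log_latent)
  X_null <- cbind(1, log_latent)
  fit_full <- suppressWarnings(
    stats::glm.fit(X_full, y, family = stats::binomial()))
  fit_null <- suppressWarnings(
    stats::glm.fit(X_null, y, family = stats::binomial()))
  mu <- fit_full$fitted.values
  separated <- !fit_full$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
  if (separated) {
    ll_full <- ridge_logistic(X_full, y)
    ll_null <- ridge_logistic(X_null, y)
    stat <- max(0, 2 * (ll_full - ll_null))
    coef_sign <- sign(stats::cov(feature, y))
  } else {
    stat <- max(fit_null$deviance - fit_full$deviance, 0)
    coef_sign <- sign(fit_full$coefficients[2L])
    if (is.na(coef_sign)) coef_sign <- 0  # feature aliased with the latent
  }
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       flagged = separated,
       coef_sign = coef_sign)
}

#' Likelihood-ratio differential accessibility with a latent depth covariate
#'
#' Per peak passing the detection gate, group membership is modeled by
#' logistic regression on the (normalized) peak value plus the log latent
#' covariate, against a null containing the log latent covariate alone;
#' the statistic `2 (ll_full - ll_null)` is referred to chi-square with 1
#' df. Perfectly separated fits fall back to a ridge-penalized logistic
#' likelihood and are flagged. Direction comes from the sign of the
#' feature coefficient: "up" (opening) means more accessible in group 1.
#'
#' @param norm_acc Cell-by-peak normalized accessibility matrix.
#' @param group_labels Two-level vector over cells.
#' @param latent Positive per-cell covariate (e.g. ATAC fragment counts).
#' @param group1 Which level is "group 1".
#' @param min_pct Detection-fraction gate (default 0.05).
#' @return `data.frame`: `feature_id`, `log2fc`, `pct_group1`,
#'   `pct_group2`, `statistic`, `p`, `p_adj`, `direction`, `flagged`.
#' @export
lr_test_da <- function(norm_acc, group_labels, latent, group1 = NULL,
                       min_pct = 0.05) {
  grp <- split_two_groups(group_labels, rownames(norm_acc), group1)
  g1 <- grp$g1
  if (!is.null(names(latent))) latent <- latent[rownames(norm_acc)]
  if (any(!is.finite(latent)) || any(latent <= 0))
    stop_input("latent covariate must be finite and positive")
  x <- as.matrix(norm_acc)
  pct1 <- colMeans(x[g1, , drop = FALSE] > 0)
  pct2 <- colMeans(x[!g1, , drop = FALSE] > 0)
  idx <- which(pmax(pct1, pct2) >= min_pct)
  if (length(idx) == 0L) return(empty_stat_table())
  y <- as.numeric(g1)
  ll <- log(latent)
  res <- lapply(idx, function(j) logistic_lrt(x[, j], y, ll))
  out <- data.frame(
    feature_id = colnames(x)[idx],
    log2fc = vapply(idx, function(j) de_fold_change(x[g1, j], x[!g1, j]),
                    numeric(1)),
    pct_group1 = pct1[idx],
    pct_group2 = pct2[idx],
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p = vapply(res, `[[`, numeric(1), "p"))
  out$p_adj <- bh_adjust(out$p)
  sign_feat <- vapply(res, `[[`, numeric(1), "coef_sign")
  out$direction <- ifelse(sign_feat >= 0, "up", "down")
  out$flagged <- vapply(res, `[[`, logical(1), "flagged")
  rownames(out) <- NULL
  out
}
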