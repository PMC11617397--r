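test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand application: sorted p * m / rank with running minimum from the top
  p <- c(0.002, 0.01, 0.04, 0.2, 0.9)
  expect_equal(bh_adjust(p), c(0.01, 0.025, 0.2 / 3, 0.25, 0.9))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  ord <- sample(100)
  p2 <- runif(100)
  expect_equal(bh_adjust(p2)[ord], bh_adjust(p2[ord]))  # order equivariance
})

test_that("rank-sum p on small groups equals exhaustive permutation enumeration", {
  # 6-cell toy, one gene expressed only in group 1
  v <- c(2.3, 1.1, 0.7, 0, 0, 0)
  g1 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- multilink:::rank_sum_test(v, g1)
  expect_equal(res$method, "exact")
  expect_equal(res$p, perm_rank_sum_p(v, g1))

  # a tied, less extreme configuration
  v2 <- c(1, 1, 0, 2, 0, 0, 3, 1)
  g2 <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  res2 <- multilink:::rank_sum_test(v2, g2)
  expect_equal(res2$p, perm_rank_sum_p(v2, g2))

  # large-sample path agrees with the tie-corrected normal approximation
  set.seed(8)
  v3 <- c(rnorm(40, 0.5), rnorm(40))
  g3 <- rep(c(TRUE, FALSE), each = 40)
  res3 <- multilink:::rank_sum_test(v3, g3)
  ref <- stats::wilcox.test(v3[g3], v3[!g3], exact = FALSE, correct = FALSE)
  expect_equal(res3$p, ref$p.value, tolerance = 1e-10)
})

test_that("wilcoxon DE gates, swaps, and degenerate cases behave", {
  qc <- default_qc()
  sub_ids <- rownames(qc$dataset$rna)[1:60]
  expr <- normalize_log1p(qc$dataset$rna[sub_ids, 1:200])
  labels <- rep(c("a", "b"), each = 30)

  # identical groups: every fold change is 0, nothing passes the gate
  dup <- rbind(as.matrix(expr)[1:30, ], as.matrix(expr)[1:30, ])
  rownames(dup) <- paste0("c", 1:60)
  none <- wilcoxon_de(dup, labels)
  expect_equal(nrow(none), 0L)

  # swapping group labels negates fold changes and flips direction
  de_ab <- wilcoxon_de(expr, labels, group1 = "a", return_all = TRUE)
  de_ba <- wilcoxon_de(expr, labels, group1 = "b", return_all = TRUE)
  shared <- intersect(de_ab$feature_id, de_ba$feature_id)
  ia <- match(shared, de_ab$feature_id); ib <- match(shared, de_ba$feature_id)
  expect_equal(de_ab$log2fc[ia], -de_ba$log2fc[ib])
  expect_equal(de_ab$p[ia], de_ba$p[ib])
  expect_true(all(de_ab$direction[ia] != de_ba$direction[ib]))

  expect_error(wilcoxon_de(expr, rep("a", 60)), "two groups")
  tiny <- expr[1:4, ]
  expect_error(wilcoxon_de(tiny, c("a", "a", "b", "b")), ">= 3 cells")
})

test_that("planted marker programs are recovered with low error", {
  sim <- default_sim()
  qc <- default_qc()
  labels <- sim$truth$cell_type[rownames(qc$dataset$rna)]
  two <- names(labels)[labels %in% c("type1", "type2")]
  sub <- subset_cells(qc$dataset, two)
  de <- wilcoxon_de(normalize_log1p(sub$rna), labels[two], group1 = "type1")
  m1 <- sim$truth$markers$type1
  m2 <- sim$truth$markers$type2
  planted <- c(m1, m2, sim$truth$true_links$gene_id)
  expect_gte(mean(m1 %in% de$feature_id[de$direction == "up"]), 0.9)
  expect_lte(mean(!de$feature_id %in% planted), 0.1)
})

test_that("LR test matches a direct-optimization fit and absorbs the latent covariate", {
  set.seed(15)
  n <- 40
  latent <- exp(rnorm(n, 8, 0.3))
  feature <- rnorm(n, 1, 0.5) + 0.4 * rep(c(1, 0), each = n / 2)
  y <- rep(c(1, 0), each = n / 2)
  fit <- multilink:::logistic_lrt(feature, y, log(latent))
  X_full <- cbind(1, feature, log(latent))
  X_null <- cbind(1, log(latent))
  stat_oracle <- 2 * (optim_logistic_ll(X_full, y) - optim_logistic_ll(X_null, y))
  expect_false(fit$flagged)
  expect_equal(fit$statistic, stat_oracle, tolerance = 1e-6)
  expect_gte(fit$statistic, -1e-8)

  # identical feature in both groups: statistic ~ 0, p ~ 1
  flat <- multilink:::logistic_lrt(rep(2, n), y, log(latent))
  expect_lt(flat$statistic, 1e-6)
  expect_gt(flat$p, 0.99)

  # accessibility an exact function of depth: the latent covariate fully
  # absorbs the group signal, leaving the feature nothing to explain
  set.seed(16)
  depth <- exp(rnorm(n, 8, 0.4)) * rep(c(2, 1), each = n / 2)
  conf <- multilink:::logistic_lrt(2 * log(depth) + 1, y, log(depth))
  expect_lt(conf$statistic, 1e-6)
  expect_gt(conf$p, 0.99)
})

test_that("lr_test_da handles separation with a flagged penalized fallback", {
  n <- 30
  set.seed(17)
  acc <- matrix(c(rep(c(3, 0), each = n / 2),            # perfectly separating
                  rnorm(n, 1, 0.3)), ncol = 2,
                dimnames = list(paste0("c", 1:n), c("sep", "ok")))
  acc <- pmax(acc, 0)
  labels <- rep(c("g1", "g2"), each = n / 2)
  latent <- stats::setNames(exp(rnorm(n, 8, 0.2)), rownames(acc))
  out <- lr_test_da(acc, labels, latent)
  expect_true(out$flagged[out$feature_id == "sep"])
  expect_false(out$flagged[out$feature_id == "ok"])
  expect_true(all(is.finite(out$p)))
  expect_true(all(out$statistic >= -1e-8))

  # label swap flips direction, p unchanged
  out2 <- lr_test_da(acc, labels, latent, group1 = "g2")
  expect_equal(out$p, out2$p, tolerance = 1e-8)
  expect_true(all(out$direction != out2$direction))
})

test_that("both tests are calibrated under a simulated global null", {
  set.seed(23)
  n <- 60; m <- 300
  x <- matrix(abs(rnorm(n * m)), n, m,
              dimnames = list(paste0("c", 1:n), paste0("f", 1:m)))
  labels <- rep(c("a", "b"), each = n / 2)
  de <- wilcoxon_de(x, labels, logfc_threshold = 0, min_pct = 0,
                    return_all = TRUE)
  rate_de <- mean(de$p_adj < 0.05)
  expect_lte(rate_de, 0.05 + 3 * sqrt(0.05 * 0.95 / m))
  latent <- stats::setNames(exp(rnorm(n, 8, 0.2)), paste0("c", 1:n))
  da <- lr_test_da(x[, 1:100], labels, latent)
  expect_lte(mean(da$p_adj < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})
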