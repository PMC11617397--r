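test_that("candidate windows follow half-open boundary rules and match brute force", {
  params <- link_params(window_bp = 1000)
  gene <- data.frame(gene_id = "g", chrom = "chr1", tss = 5000L, strand = "+")
  peaks <- data.frame(
    peak_id = c("covers_tss", "at_upper_edge", "just_inside_upper",
                "at_lower_edge", "just_inside_lower", "other_chrom"),
    chrom = c(rep("chr1", 5), "chr2"),
    start = c(4950L, 5500L, 5499L, 4400L, 4401L, 4950L),
    end = c(5050L, 5600L, 5599L, 4500L, 4501L, 5050L))
  cand <- candidate_peaks(gene, peaks, params)
  expect_setequal(cand$peak_id, c("covers_tss", "just_inside_upper",
                                  "just_inside_lower"))
  expect_equal(cand$tss_distance[cand$peak_id == "covers_tss"], 0L)
  expect_equal(cand$tss_distance[cand$peak_id == "just_inside_upper"], 499L)
  expect_equal(cand$tss_distance[cand$peak_id == "just_inside_lower"], -499L)

  # minus strand flips the sign (downstream positive)
  gene_m <- gene; gene_m$strand <- "-"
  cand_m <- candidate_peaks(gene_m, peaks, params)
  expect_equal(cand_m$tss_distance[cand_m$peak_id == "just_inside_upper"], -499L)

  # brute-force oracle over a generated layout
  cfg <- sim_config(n_genes = 20L, n_links = 10L, seed = 7L)
  layout <- make_genome_layout(cfg)
  lp <- link_params(window_bp = cfg$window_bp)
  for (i in c(1, 5, 20)) {
    gene_i <- layout$genes[i, ]
    cand_i <- candidate_peaks(gene_i, layout$peaks, lp)
    w2 <- lp$window_bp / 2
    manual <- layout$peaks$peak_id[
      layout$peaks$chrom == gene_i$chrom &
        layout$peaks$start < gene_i$tss + w2 &
        layout$peaks$end > gene_i$tss - w2]
    expect_setequal(cand_i$peak_id, manual)
  }
})

test_that("RF weights normalize, rank causal peaks first, and degrade to null", {
  params <- link_params()
  set.seed(41)
  n <- 300
  A <- matrix(rpois(n * 6, 3), n, 6, dimnames = list(NULL, paste0("p", 1:6)))
  x <- 1.2 * A[, 3] + rnorm(n, 0, 0.8)
  w <- fit_gene_links_rf(x, A, params, seed = 2)
  expect_equal(sum(w), 1)
  expect_equal(names(which.max(w)), "p3")

  # constant expression is flagged untestable with zero weights
  w0 <- fit_gene_links_rf(rep(1, n), A, params, seed = 2)
  expect_true(isTRUE(attr(w0, "untestable")))
  expect_equal(sum(w0), 0)

  # same seed reproduces, different seed perturbs
  expect_identical(w, fit_gene_links_rf(x, A, params, seed = 2))
  expect_false(identical(w, fit_gene_links_rf(x, A, params, seed = 3)))

  # iid null: no dominant weight, top rank unstable across seeds
  y <- rnorm(n)
  tops <- vapply(1:10, function(s)
    names(which.max(fit_gene_links_rf(y, A, params, seed = s))), character(1))
  expect_gt(length(unique(tops)), 1L)
  wn <- fit_gene_links_rf(y, A, params, seed = 1)
  expect_lt(max(wn), 3 / ncol(A))
})

test_that("linear weights recover exact coefficients and flag rank deficiency", {
  # orthonormal design, x = 2 a1: closed form w = (2, 0)
  A <- cbind(a1 = c(1, 0, 0, 0), a2 = c(0, 1, 0, 0))
  x <- 2 * A[, 1]
  w <- fit_gene_links_linear(x, A)
  expect_equal(unname(w), c(2, 0), tolerance = 1e-10)

  # pure noise: small coefficients, F test non-significant
  set.seed(5)
  A2 <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, paste0("a", 1:3)))
  x2 <- rnorm(200)
  w2 <- fit_gene_links_linear(x2, A2)
  f <- summary(stats::lm(x2 ~ A2))$fstatistic
  expect_gt(stats::pf(f[1], f[2], f[3], lower.tail = FALSE), 0.05)
  expect_lt(max(abs(w2)), 0.3)

  # duplicated column: rank-deficient, ridged and flagged
  A3 <- cbind(a1 = A2[, 1], a2 = A2[, 1])
  w3 <- fit_gene_links_linear(x2, A3)
  expect_true(isTRUE(attr(w3, "ridged")))
  expect_true(all(is.finite(w3)))
})

test_that("top-percentile selection counts and tie rules match an independent quantile", {
  params <- link_params()
  # 100 distinct weights: exactly the top 5 selected
  w <- stats::setNames(seq(0.001, 0.1, length.out = 100), paste0("p", 1:100))
  sel <- select_top_links(w, params)
  expect_setequal(sel, paste0("p", 96:100))
  # 20 equal weights: all tied at the threshold, all selected
  we <- stats::setNames(rep(0.05, 20), paste0("q", 1:20))
  expect_length(select_top_links(we, params), 20L)
  # independent quantile implementation agreement on random draws
  set.seed(6)
  for (i in 1:20) {
    wr <- stats::setNames(runif(sample(5:40, 1)), NULL)
    names(wr) <- paste0("r", seq_along(wr))
    sel_r <- select_top_links(wr, params)
    srt <- sort(wr)
    h <- (length(wr) - 1) * 0.95 + 1
    thr <- srt[floor(h)] + (h - floor(h)) * (srt[min(length(wr), floor(h) + 1)] - srt[floor(h)])
    expect_setequal(sel_r, names(wr)[wr >= thr])
  }
})

test_that("enhancer distance classes reproduce the printed boundaries", {
  expect_equal(classify_enhancer_distance(0), "TSS_overlap")
  expect_equal(classify_enhancer_distance(c(1, 50, 200)), rep("none", 3))
  expect_equal(classify_enhancer_distance(c(201, 1000, 2000)), rep("pELS", 3))
  expect_equal(classify_enhancer_distance(c(2001, 50000)), rep("dELS", 2))
  # sign does not matter
  expect_equal(classify_enhancer_distance(c(-201, -2000, -2001)),
               c("pELS", "pELS", "dELS"))
})

test_that("cCRE overlap uses half-open semantics and matches an all-pairs scan", {
  peaks <- data.frame(peak_id = c("pA", "pB"), chrom = "chr1",
                      start = c(100L, 100L), end = c(200L, 200L))
  links <- data.frame(gene_id = "g", peak_id = c("pA", "pB"))
  ccre1 <- data.frame(peak_id = "e1", chrom = "chr1", start = 199L, end = 300L)
  ccre2 <- data.frame(peak_id = "e2", chrom = "chr1", start = 200L, end = 300L)
  expect_true(all(annotate_ccre_overlap(links, peaks, ccre1)$ccre_overlap))
  expect_false(any(annotate_ccre_overlap(links, peaks, ccre2)$ccre_overlap))

  set.seed(12)
  n <- 50
  pk <- data.frame(peak_id = paste0("p", 1:n), chrom = "chr1",
                   start = as.integer(sample(1e5, n)))
  pk$end <- pk$start + 400L
  cc <- data.frame(peak_id = paste0("e", 1:n), chrom = "chr1",
                   start = as.integer(sample(1e5, n)))
  cc$end <- cc$start + 350L
  lk <- data.frame(gene_id = "g", peak_id = pk$peak_id)
  got <- annotate_ccre_overlap(lk, pk, cc)$ccre_overlap
  manual <- vapply(seq_len(n), function(i)
    any(pk$start[i] < cc$end & pk$end[i] > cc$start), logical(1))
  expect_equal(got, manual)

  expect_warning(
    annotate_ccre_overlap(lk, pk,
                          data.frame(peak_id = "e", chrom = "1",
                                     start = 1L, end = 10L)),
    "harmonize")
})

test_that("inference recovers planted links within the window and is cell-order invariant", {
  sim <- default_sim()
  qc <- default_qc()
  tl <- sim$truth$true_links
  linked <- sim$dataset$genes[sim$dataset$genes$gene_id %in% tl$gene_id, ]
  params <- link_params(seed = 13L)
  rl <- infer_regulatory_links(qc$dataset, params, genes = linked)
  truth_pairs <- paste(tl$gene_id, tl$peak_id)
  found_pairs <- paste(rl$links$gene_id, rl$links$peak_id)
  expect_gte(mean(truth_pairs %in% found_pairs), 0.8)
  expect_true(all(abs(rl$links$tss_distance) <= params$window_bp / 2))
  expect_true(all(rl$links$percentile_rank >= params$select_percentile))

  # jointly permuting cell order leaves the output identical
  set.seed(3)
  perm <- sample(rownames(qc$dataset$rna))
  ds_perm <- subset_cells(qc$dataset, perm)
  rl_perm <- infer_regulatory_links(ds_perm, params, genes = linked)
  expect_equal(rl$links, rl_perm$links)

  # genes with too few candidates are skipped and listed
  sparse_genes <- sim$dataset$genes[sim$dataset$genes$chrom == "chrM", ]
  rl_m <- suppressWarnings(
    infer_regulatory_links(qc$dataset, params, genes = sparse_genes))
  expect_equal(nrow(rl_m$links), 0L)
  expect_true(all(rl_m$gene_info$status == "too_few_candidates"))
})

test_that("RF and linear-oracle rankings agree on multi-weight linear data", {
  # linear generative model with graded weights over every peak, so the
  # full candidate ranking is meaningful (with a single causal peak the
  # decoy ranks are pure noise and rank agreement is undefined)
  params <- link_params(seed = 1L)
  set.seed(90)
  rhos <- vapply(1:20, function(k) {
    n <- 450L; p <- 10L
    A <- vapply(stats::runif(p, 1, 6), function(r) stats::rpois(n, r),
                numeric(n))
    colnames(A) <- paste0("pk", seq_len(p))
    w_true <- 2 ^ seq(0, -4.5, length.out = p)
    signal <- drop(A %*% w_true)
    x <- signal + stats::rnorm(n, 0, stats::sd(signal) * 0.3)
    stats::cor(rank(fit_gene_links_rf(x, A, params, seed = k)),
               rank(abs(fit_gene_links_linear(x, A))), method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.7)
})

test_that("increasing the planted weight never decreases the causal peak's weight", {
  weights_at <- vapply(c(0.5, 1.0, 1.5, 2.0), function(wv) {
    cfg <- sim_config(n_cells = 250L, n_genes = 60L, n_links = 10L,
                      link_weight_range = c(wv, wv), doublet_rate = 0,
                      lowq_rate = 0, seed = 77L)
    sim <- simulate_dataset(cfg)
    expr <- normalize_log1p(sim$dataset$rna)
    acc <- as.matrix(normalize_log1p(sim$dataset$atac))
    tl <- sim$truth$true_links
    params <- link_params(seed = 77L)
    mean(vapply(seq_len(nrow(tl)), function(k) {
      gene <- sim$dataset$genes[sim$dataset$genes$gene_id == tl$gene_id[k], ]
      cand <- candidate_peaks(gene, sim$dataset$peaks, params)
      w <- fit_gene_links_rf(as.numeric(expr[, gene$gene_id]),
                             acc[, cand$peak_id, drop = FALSE], params,
                             seed = k)
      unname(w[tl$peak_id[k]])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(weights_at) >= 0))
})
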