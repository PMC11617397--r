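#' Configuration for the synthetic paired multiome generator
#'
#' Defaults define the reference simulation scenario used throughout the
#' test-suite: 500 cells in 3 types across 6 samples (2 per condition),
#' 1000 nuclear genes plus 10 mitochondrial pseudo-genes (a transcriptome large enough that healthy nuclei clear the 400-feature QC floor), 20 genes with one
#' planted causal peak each at weight 1.5, 9 in-window decoy peaks and 1
#' far decoy per gene, and a 500 kb total window span.
#'
#' @param n_cells Number of cells.
#' @param n_types Number of planted cell types.
#' @param n_genes Number of nuclear genes.
#' @param n_mito_genes Number of mitochondrial pseudo-genes (ids prefixed
#'   `MT-`) that absorb each cell's drawn mitochondrial fraction.
#' @param n_links Number of genes given one causal peak each.
#' @param link_weight_range Length-2 numeric; planted weights are drawn
#'   uniformly from this range (equal endpoints give a fixed weight).
#' @param decoys_in_window Decoy peaks placed inside each gene's window.
#' @param decoys_out_window Decoy peaks placed beyond each gene's window.
#' @param window_bp Total window span centered on the TSS (bp).
#' @param rna_library_size Log-normal parameters (`meanlog`, `sdlog`) for
#'   per-cell RNA library size.
#' @param atac_depth Log-normal parameters for per-cell fragments in peaks.
#' @param nb_dispersion Negative-binomial dispersion of RNA counts
#'   (variance = mu + dispersion * mu^2).
#' @param mito_fraction Beta parameters (`shape1`, `shape2`) for the
#'   per-cell mitochondrial fraction.
#' @param doublet_rate,lowq_rate Fractions of cells converted to doublets /
#'   low-quality artifacts by [spike_artifacts()].
#' @param n_samples Number of samples; conditions are assigned round-robin
#'   over `conditions`, regions alternate over `regions`, and each sample
#'   receives a log-normal ATAC depth offset (sd `sample_depth_sdlog`) so
#'   the per-sample fragment ceiling is meaningful.
#' @param conditions,regions Label pools for samples.
#' @param sample_depth_sdlog Log-sd of per-sample ATAC depth offsets.
#' @param marker_genes_per_type,marker_fold Planted expression programs:
#'   each cell type elevates `marker_genes_per_type` genes (drawn from the
#'   upper half of baseline expression) by `marker_fold`.
#' @param peak_width Width of every simulated peak (bp).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 500L, n_types = 3L, n_genes = 1000L,
                       n_mito_genes = 10L, n_links = 20L,
                       link_weight_range = c(1.5, 1.5),
                       decoys_in_window = 9L, decoys_out_window = 1L,
                       window_bp = 500000L,
                       rna_library_size = list(meanlog = log(2500), sdlog = 0.35),
                       atac_depth = list(meanlog = log(3000), sdlog = 0.4),
                       nb_dispersion = 0.1,
                       mito_fraction = list(shape1 = 2, shape2 = 38),
                       doublet_rate = 0.05, lowq_rate = 0.05,
                       n_samples = 6L,
                       conditions = c("control", "FCD_IIa", "FCD_IIb"),
                       regions = c("frontal", "temporal"),
                       sample_depth_sdlog = 0.15,
                       marker_genes_per_type = 15L, marker_fold = 2,
                       peak_width = 500L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_cells > 0, n_types > 0, n_genes > 0, n_mito_genes >= 0,
            n_links >= 0, decoys_in_window >= 0, decoys_out_window >= 1,
            window_bp > 0, peak_width > 0, nb_dispersion > 0,
            length(link_weight_range) == 2, all(link_weight_range >= 0),
            n_samples >= 1)
  if (n_links > n_genes) stop_input("n_links must be <= n_genes")
  if (doublet_rate < 0 || doublet_rate > 1 || lowq_rate < 0 || lowq_rate > 1)
    stop_input("rates must lie in [0, 1]")
  if (doublet_rate + lowq_rate > 1)
    stop_input("doublet_rate + lowq_rate must not exceed 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Lay out a synthetic genome: genes, peaks, and planted causal links
#'
#' One synthetic chromosome (`chrS`) with genes evenly spaced far enough
#' apart that windows never overlap. The first `n_links` genes each receive
#' exactly one causal peak placed uniformly within +/- `window_bp / 2` of
#' the TSS; every nuclear gene receives `decoys_in_window` decoy peaks in
#' its window and `decoys_out_window` decoys beyond it (in the spacer
#' between windows, inside no gene's window). Mitochondrial pseudo-genes
#' live on `chrM` with no peaks.
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `peaks`, and `true_links`
#'   (`gene_id`, `peak_id`, `weight`).
#' @export
make_genome_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "layout"), {
    w2 <- config$window_bp / 2
    margin <- 50000L
    spacing <- config$window_bp + 2L * margin
    if (spacing <= config$window_bp)
      stop_input("window too large for chromosome span")
    n_g <- config$n_genes
    tss <- as.integer(round(spacing / 2 + (seq_len(n_g) - 1L) * spacing))
    genes <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_g)),
      chrom = "chrS",
      tss = tss,
      strand = rep_len(c("+", "-"), n_g))
    if (config$n_mito_genes > 0) {
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("MT-%d", seq_len(config$n_mito_genes)),
        chrom = "chrM",
        tss = as.integer(seq(0L, by = 1000L, length.out = config$n_mito_genes)),
        strand = "+"))
    }
    pw <- config$peak_width
    starts <- integer(0); owner <- character(0); role <- character(0)
    for (i in seq_len(n_g)) {
      lo <- tss[i] - w2; hi <- tss[i] + w2
      if (i <= config$n_links) {
        starts <- c(starts, round(stats::runif(1, lo, hi - pw)))
        owner <- c(owner, genes$gene_id[i]); role <- c(role, "causal")
      }
      if (config$decoys_in_window > 0) {
        starts <- c(starts, round(stats::runif(config$decoys_in_window, lo, hi - pw)))
        owner <- c(owner, rep(genes$gene_id[i], config$decoys_in_window))
        role <- c(role, rep("decoy_in", config$decoys_in_window))
      }
      # spacer between this window's end and the next window's start
      starts <- c(starts, round(stats::runif(config$decoys_out_window,
                                             hi + 1000, hi + margin - pw)))
      owner <- c(owner, rep(genes$gene_id[i], config$decoys_out_window))
      role <- c(role, rep("decoy_out", config$decoys_out_window))
    }
    ord <- order(starts)
    peaks <- data.frame(
      peak_id = sprintf("peak_%05d", seq_along(starts)),
      chrom = "chrS",
      start = as.integer(starts[ord]),
      end = as.integer(starts[ord] + pw),
      owner_gene = owner[ord],
      role = role[ord])
    causal <- peaks[peaks$role == "causal", , drop = FALSE]
    true_links <- data.frame(
      gene_id = causal$owner_gene,
      peak_id = causal$peak_id,
      weight = stats::runif(nrow(causal), config$link_weight_range[1],
                            config$link_weight_range[2]))
    true_links <- true_links[order(true_links$gene_id), , drop = FALSE]
    rownames(true_links) <- NULL
    list(genes = genes, peaks = peaks, true_links = true_links)
  })
}

#' Simulate paired RNA + ATAC counts over a genome layout
#'
#' ATAC: per cell type each peak draws a relative openness once; per-cell
#' counts are Poisson with rate proportional to the cell's drawn depth (a
#' log-normal with a per-sample offset) times the type's openness. RNA: a
#' gene's log-mean is its baseline plus, for linked genes, the planted
#' weight times the standardized log1p depth-normalized accessibility of
#' its causal peak in that cell; counts are negative binomial at the drawn
#' library size. Mitochondrial pseudo-genes receive each cell's Beta-drawn
#' mitochondrial fraction of the library. Cell-type marker programs elevate
#' marker genes `marker_fold`-fold in their own type.
#'
#' @param layout From [make_genome_layout()].
#' @param config The same [sim_config()].
#' @return List with `dataset` (a `multiome_dataset`) and `truth`
#'   (`cell_type`, `is_doublet`, `is_lowq` per cell; `true_links`;
#'   `markers` per type; recorded per-cell totals).
#' @export
simulate_multiome <- function(layout, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "counts"), {
    n <- config$n_cells
    cell_id <- sprintf("cell_%04d", seq_len(n))
    type <- sample(sprintf("type%d", seq_len(config$n_types)), n, replace = TRUE)
    sample_id <- sprintf("S%d", rep_len(seq_len(config$n_samples), n))
    cond <- rep_len(config$conditions, config$n_samples)[match(sample_id, sprintf("S%d", seq_len(config$n_samples)))]
    region <- rep_len(config$regions, config$n_samples)[as.integer(sub("S", "", sample_id))]
    batch <- sprintf("batch%d", 1L + (as.integer(sub("S", "", sample_id)) - 1L) %/%
                       max(1L, config$n_samples %/% 2L))

    nuclear <- layout$genes$gene_id[layout$genes$chrom != "chrM"]
    mito <- layout$genes$gene_id[layout$genes$chrom == "chrM"]
    peaks <- layout$peaks
    n_peaks <- nrow(peaks)
    types <- sort(unique(type))

    # --- ATAC ---------------------------------------------------------
    sample_offset <- stats::rlnorm(config$n_samples,
                                   meanlog = 0, sdlog = config$sample_depth_sdlog)
    names(sample_offset) <- sprintf("S%d", seq_len(config$n_samples))
    depth <- stats::rlnorm(n, config$atac_depth$meanlog,
                           config$atac_depth$sdlog) * sample_offset[sample_id]
    openness <- matrix(stats::rlnorm(n_peaks * length(types), 0, 1),
                       nrow = n_peaks,
                       dimnames = list(peaks$peak_id, types))
    open_frac <- sweep(openness, 2, colSums(openness), "/")
    atac <- matrix(0L, nrow = n, ncol = n_peaks,
                   dimnames = list(cell_id, peaks$peak_id))
    for (t in types) {
      idx <- which(type == t)
      lam <- outer(depth[idx], open_frac[, t])
      atac[idx, ] <- stats::rpois(length(lam), lam)
    }

    # --- planted link term -------------------------------------------
    fip <- pmax(rowSums(atac), 1)
    link_shift <- matrix(0, nrow = n, ncol = length(nuclear),
                         dimnames = list(cell_id, nuclear))
    tl <- layout$true_links
    if (nrow(tl)) {
      for (k in seq_len(nrow(tl))) {
        abar <- log1p(atac[, tl$peak_id[k]] / fip * 1e4)
        s <- stats::sd(abar)
        z <- if (is.na(s) || s == 0) rep(0, n) else (abar - mean(abar)) / s
        link_shift[, tl$gene_id[k]] <- tl$weight[k] * z
      }
    }

    # --- RNA ----------------------------------------------------------
    base <- stats::rlnorm(length(nuclear), meanlog = 0, sdlog = 0.7)
    names(base) <- nuclear
    markers <- list()
    marker_mult <- matrix(1, nrow = length(nuclear), ncol = length(types),
                          dimnames = list(nuclear, types))
    upper_half <- nuclear[base >= stats::median(base)]
    # markers drawn from well-expressed genes so planted programs can reach
    # the top ranks a cell-level AUC looks at; disjoint across types
    pool <- setdiff(upper_half, tl$gene_id)
    for (t in types) {
      pick <- sample(pool, min(config$marker_genes_per_type, length(pool)))
      pool <- setdiff(pool, pick)
      markers[[t]] <- pick
      marker_mult[pick, t] <- config$marker_fold
    }
    lib <- stats::rlnorm(n, config$rna_library_size$meanlog,
                         config$rna_library_size$sdlog)
    mfrac <- stats::rbeta(n, config$mito_fraction$shape1,
                          config$mito_fraction$shape2)
    size <- 1 / config$nb_dispersion
    rna <- matrix(0L, nrow = n, ncol = length(nuclear) + length(mito),
                  dimnames = list(cell_id, c(nuclear, mito)))
    for (t in types) {
      idx <- which(type == t)
      # mean-preserving link factor: normalizing exp(w z) by its within-type
      # mean keeps each linked gene's average library share at its baseline,
      # so planted links add covariation without shifting compositional
      # baselines between types
      lf <- exp(link_shift[idx, , drop = FALSE])
      lf <- sweep(lf, 2, colMeans(lf), "/")
      u <- sweep(lf, 2, base * marker_mult[, t], "*")
      prop <- u / rowSums(u)
      mu <- prop * (lib[idx] * (1 - mfrac[idx]))
      rna[idx, nuclear] <- stats::rnbinom(length(mu), mu = mu, size = size)
    }
    if (length(mito)) {
      mito_w <- stats::rlnorm(length(mito), 0, 0.5)
      mito_w <- mito_w / sum(mito_w)
      mu_m <- outer(lib * mfrac, mito_w)
      rna[, mito] <- stats::rnbinom(length(mu_m), mu = mu_m, size = size)
    }

    # --- metadata -----------------------------------------------------
    frip <- stats::runif(n, 0.55, 0.75)
    cells <- data.frame(
      cell_id = cell_id, sample_id = sample_id, condition = cond,
      batch = batch, region = region,
      n_fragments = as.integer(ceiling(fip / frip)),
      fragments_in_peaks = as.integer(rowSums(atac)),
      nucleosome_signal = stats::rlnorm(n, log(0.8), 0.25),
      tss_enrichment = stats::rlnorm(n, log(4), 0.25))

    dataset <- multiome_dataset(
      rna = count_matrix(rna, "rna"),
      atac = count_matrix(atac, "atac"),
      cells = cells,
      genes = layout$genes,
      peaks = layout$peaks[, c("peak_id", "chrom", "start", "end")])

    truth <- list(
      cell_type = stats::setNames(type, cell_id),
      is_doublet = stats::setNames(rep(FALSE, n), cell_id),
      is_lowq = stats::setNames(rep(FALSE, n), cell_id),
      true_links = layout$true_links,
      markers = markers,
      rna_totals = rowSums(rna),
      atac_totals = rowSums(atac),
      library_size = stats::setNames(lib, cell_id),
      mito_fraction = stats::setNames(mfrac, cell_id))
    list(dataset = dataset, truth = truth)
  })
}

#' Spike QC artifacts (doublets and low-quality nuclei) into a clean dataset
#'
#' Doublets: `round(doublet_rate * n)` cells are replaced by the
#' element-wise sum of two random clean parents' counts (both modalities),
#' binomially downsampled to 1.8x the median clean library size.
#' Low-quality nuclei: `round(lowq_rate * n)` cells; half are RNA-thinned
#' to ~250 total UMIs (below the 500-UMI floor), half get their ATAC
#' fragment count inflated 10x above the sample mean (beyond the
#' per-sample mean + 2 SD ceiling). Flags are mutually exclusive and
#' recorded in the returned ground truth.
#'
#' @param sim List with `dataset` and `truth`, from [simulate_multiome()].
#' @param config The same [sim_config()].
#' @return Same shape as [simulate_multiome()], flags updated.
#' @export
spike_artifacts <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  dataset <- sim$dataset; truth <- sim$truth
  n <- nrow(dataset$rna)
  n_dbl <- round(config$doublet_rate * n)
  n_lowq <- round(config$lowq_rate * n)
  if (n_dbl + n_lowq > n)
    stop_input("artifact rates exceed the available cells")
  if (n_dbl == 0 && n_lowq == 0) return(sim)
  with_seed(derive_seed(config$seed, "artifacts"), {
    rna <- as.matrix(dataset$rna)
    atac <- as.matrix(dataset$atac)
    cells <- dataset$cells
    picked <- sample(n, n_dbl + n_lowq)
    dbl_idx <- picked[seq_len(n_dbl)]
    lowq_idx <- picked[n_dbl + seq_len(n_lowq)]
    clean <- setdiff(seq_len(n), picked)

    if (n_dbl > 0) {
      # parents drawn from the pre-spike counts so the construction is
      # well defined at any doublet rate
      rna0 <- rna; atac0 <- atac; frag0 <- cells$n_fragments
      pool_for <- function(i) if (length(clean)) clean else setdiff(seq_len(n), i)
      lib_ref <- if (length(clean)) rowSums(rna0[clean, , drop = FALSE]) else rowSums(rna0)
      target <- round(1.8 * stats::median(lib_ref))
      for (i in dbl_idx) {
        parents <- sample(pool_for(i), 2L)
        s_rna <- rna0[parents[1L], ] + rna0[parents[2L], ]
        tot <- sum(s_rna)
        if (tot > target)
          s_rna <- stats::rbinom(length(s_rna), s_rna, target / tot)
        rna[i, ] <- s_rna
        atac[i, ] <- atac0[parents[1L], ] + atac0[parents[2L], ]
        cells$n_fragments[i] <- frag0[parents[1L]] + frag0[parents[2L]]
        cells$fragments_in_peaks[i] <- sum(atac[i, ])
      }
    }
    if (n_lowq > 0) {
      thin <- lowq_idx[seq_len(ceiling(n_lowq / 2))]
      blow <- setdiff(lowq_idx, thin)
      for (i in thin) {
        tot <- sum(rna[i, ])
        if (tot > 0) rna[i, ] <- stats::rbinom(ncol(rna), rna[i, ], min(1, 250 / tot))
      }
      if (length(blow)) {
        mean_frag <- tapply(cells$n_fragments, cells$sample_id, mean)
        cells$n_fragments[blow] <-
          as.integer(round(10 * mean_frag[cells$sample_id[blow]]))
        cells$fragments_in_peaks[blow] <- pmin(cells$fragments_in_peaks[blow],
                                               cells$n_fragments[blow])
      }
    }
    truth$is_doublet[dbl_idx] <- TRUE
    truth$is_lowq[lowq_idx] <- TRUE
    truth$rna_totals <- rowSums(rna)
    truth$atac_totals <- rowSums(atac)
    dataset <- multiome_dataset(
      rna = count_matrix(rna, "rna"),
      atac = count_matrix(atac, "atac"),
      cells = cells, genes = dataset$genes, peaks = dataset$peaks)
    list(dataset = dataset, truth = truth)
  })
}

#' One-call synthetic multiome: layout, counts, and spiked artifacts
#'
#' @param config A [sim_config()]; defaults give the reference scenario.
#' @return List with `dataset`, `truth`, and `layout`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  layout <- make_genome_layout(config)
  sim <- simulate_multiome(layout, config)
  sim <- spike_artifacts(sim, config)
  sim$layout <- layout
  sim
}
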