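# multilink

Paired single-nuclei RNA + ATAC (multiome) assays measure gene expression
and chromatin accessibility in the same nucleus, which makes it possible
to ask which open-chromatin peaks drive which genes. `multilink`
implements the quantitative core of such an analysis — built for studies
of focal cortical dysplasia-like designs with lesion and control samples,
but agnostic to the biology — as a tested R package plus a sequence of
analysis drivers:

* **Quality control** with the printed strict thresholds
  (400 < nFeatures < 7000, 500 < UMI < 50000, percent.mt < 15;
  1000 < ATAC fragments < α with a per-sample ceiling α = mean + 2 SD;
  nucleosome signal < 2; TSS enrichment rule with configurable direction).
* **Gene-set activity**: bin-matched module scores and ranking-based AUC
  over the top 5% of each cell's expression ranks, with active cells
  called against a bin-matched random null.
* **Cell-type composition testing** across biological replicates:
  arcsin-√ proportions, OLS per cell type on condition + region, BH
  across cell types.
* **Differential tests**: Wilcoxon rank-sum DE (log2fc gate 0.25,
  detection gate 10%, BH < 0.05) and logistic likelihood-ratio
  differential accessibility with ATAC fragment counts as a latent
  covariate.
* **Cis-regulatory link inference** — the central method. For each gene
  `g` with candidate peaks in a 500 kb window around its TSS, the linear
  model

  x_gi = Σ_j w_j a_ji + ε_i

  is fit by a 200-tree random-forest regression; per-peak weights are the
  normalized impurity importances, peaks at or above the per-gene 95th
  weight percentile become links, and links are classified by TSS
  distance (pELS: 200 bp < d ≤ 2 kb; dELS: d > 2 kb) and ENCODE-style
  cCRE overlap.

Because real cohort results require tens of thousands of patient nuclei,
the package ships a **synthetic multiome generator** that plants cell
types, marker programs, doublets, low-quality nuclei, and true linear
accessibility→expression links — every stage is validated against that
ground truth and against independent brute-force oracles.

## Worked example

```r
library(multilink)

cfg <- sim_config(seed = 13L)        # 500 cells, 20 planted links at w = 1.5
sim <- simulate_dataset(cfg)
qc  <- apply_qc(sim$dataset)
rl  <- infer_regulatory_links(qc$dataset, link_params(seed = 13L))

tl <- sim$truth$true_links
mean(paste(tl$gene_id, tl$peak_id) %in%
     paste(rl$links$gene_id, rl$links$peak_id))
```

Running the numbered drivers reproduces the whole workflow and prints the
stage summaries (tables under `results/pipeline/`, regenerable count
matrices under `scratch/pipeline_data/`):

```
$ Rscript analysis/01_simulate.R
simulated 500 cells x 1010 genes / 10020 peaks; 20 planted links, 25 doublets, 25 low-quality nuclei
$ Rscript analysis/02_qc.R
kept 457 / 500 cells; planted low-quality sensitivity 1.000
$ Rscript analysis/03_signatures.R
activity threshold 0.2258 (q99 of bin-matched null)
active: 59.9% of type-1 cells, 1.0% of the rest
$ Rscript analysis/05_differential.R
DE: 32 genes at BH < 0.05; 15/15 type-1 markers recovered up
$ Rscript analysis/06_links.R
links: 1000 selected over 1000 genes; planted-link recall 1.00
```

Reading the numbers: QC caught every planted low-quality nucleus while
keeping 91% of all cells; the planted type-1 expression program is called
active in 60% of type-1 cells versus 1% elsewhere (a two-fold program in
2500-UMI cells is resolution-limited — see the methods vignette); the
rank-sum test recovers all 15 planted markers; and the forest ranks the
true causal peak into the top 5% for all 20 linked genes, with zero links
escaping the 500 kb window.

## Layout

```
R/                  package code (io, simulate, qc, signatures,
                    composition, differential, links, pipeline)
analysis/01..06.R   narrative drivers: simulate → qc → score →
                    composition → de/da → links
scripts/acceptance.R  from-scratch recomputation of headline quantities
tests/testthat/     unit, property, and acceptance tests
vignettes/          methods vignette (models, parameters, limitations)
```

Input formats: Matrix Market directories with features/barcodes sidecars
(10x layout, orientation auto-detected), BED3/BED4 (0-based half-open
everywhere), TSV gene annotation (`gene_id`, `chrom`, `tss`, `strand`)
and per-cell metadata; outputs are TSV tables plus BEDPE for links.
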