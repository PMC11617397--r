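Package: multilink
Title: Paired Single-Nuclei Multiome QC, Scoring, and Cis-Regulatory Link Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, gene-set activity scoring, cell-composition
    testing, differential expression/accessibility, and random-forest
    inference of cis-regulatory peak-to-gene links for paired single-nuclei
    RNA + ATAC (multiome) count data. Includes a synthetic multiome
    generator with planted cell types, QC artifacts, and linear
    accessibility-to-expression links so every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    ranger,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
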