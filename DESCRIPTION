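Package: germcomp
Title: Enhancer Decommissioning and Germline Competence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis toolkit for chromatin-level germline
    competence studies in the mouse PGCLC (primordial germ cell-like cell)
    differentiation system. Defines stage-specific gene sets and a
    cell-to-cell transcriptional noise statistic from single-cell UMI
    counts, builds distal enhancer catalogs from histone-mark peaks with
    capture Hi-C anchor linking, classifies partially decommissioned
    (Group I) enhancers by replicate-consistent H3K4me1 stage ratios,
    quantifies 1x-normalized chromatin signal in fixed windows with paired
    signed-rank effect sizes, and measures single-cell CpG-methylation
    heterogeneity as pairwise dissimilarity over shared sites. Ships a
    seeded synthetic-data generator with planted ground truth so every
    stage of the pipeline is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
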