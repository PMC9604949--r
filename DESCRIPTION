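Package: decompactr
Title: Chromatin Decompaction and Stochastic Transcription Time-Course Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing paired single-cell RNA-seq and bulk/single-cell
    ATAC-seq time courses of differentiating progenitor cells. Implements
    cell and gene quality-control filters for UMI count matrices, the index
    for critical transitions (Ic) computed from thresholded gene-gene and
    cell-cell Pearson correlations within cell clusters, cross-donor Z-score
    differential expression, donor-reproducible ATAC peak intersection,
    multi-category genomic annotation of peaks, promoter open/closed
    configuration classification between time points, peak presence-pattern
    trajectories, union-region fold changes, transcription-factor-target
    enrichment with two-sided Fisher exact tests, and cell-sharing statistics
    for single-cell accessibility matrices. A synthetic-data module generates
    all pipeline inputs from a two-state bursting model with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
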