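Package: atacdyn
Title: Differential Chromatin Accessibility and Kinetics of Pioneer-Factor
    Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of ATAC-seq depletion experiments for
    pioneer transcription factors (OCT4/SOX2 in mouse embryonic stem
    cells): peak preprocessing and BED interval handling, fragment
    counting and TMM normalization of region-by-sample count matrices,
    empirical-Bayes moderated linear models for differential
    accessibility with Benjamini-Hochberg FDR control, classification of
    regulatory elements into factor-dependent and co-dependent sets,
    k-means clustering of cell-cycle fold-change profiles, and
    exponential-decay fitting of accessibility-loss and protein-
    degradation time courses with half-life estimation. Includes a
    negative-binomial synthetic-data generator emulating the supported
    experimental designs for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
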