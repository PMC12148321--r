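Package: werscreen
Title: Screening Seasonal Time-Series Data for H3K27me3-Associated
    Week-Scale Environmental Response Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to screen genome-wide seasonal histone-modification and
    transcriptome time series for promoters whose repressive H3K27me3 levels
    change on a week-to-season scale in anti-phase with gene expression.
    Implements strand-aware promoter/genic window arithmetic and RPKM
    aggregation, cosinor rhythmometry with an F-test, a log2 peak-to-trough
    amplitude statistic, a negative-binomial seasonal likelihood-ratio test,
    smoothing-spline monthly estimation, Spearman anti-correlation filters,
    multi-window robustness and candidate ranking, Fisher-exact
    upstream-overlap enrichment, an affine-gap global nucleotide aligner with
    percent-identity reporting, colorimetric quantification of GUS-stained
    tissue images, and delta-Ct relative quantification for RT-qPCR and
    ChIP-qPCR. A synthetic-data module generates annotation, seasonal signal
    matrices, stained-tissue images and sequence pairs with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    Rcpp,
    png,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    knitr
Config/testthat/edition: 3
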