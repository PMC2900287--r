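Package: aiscan
Title: Detection of Allelic Imbalance Regions from High-Density Allelic
    Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Signal-processing methods for detecting genomic regions of
    allelic imbalance (AI) from dense site-by-sample allelic expression
    measurements, such as those obtained by hybridizing cDNA to SNP
    genotyping arrays. Implements four detectors: simple smoothing of the
    allelic log-ratio, an expression-binned Z-score approach with greedy
    non-overlapping window selection, a single-sample ergodic hidden
    Markov model with distance-dependent transition matrices obtained via
    matrix fractional powers, and a multi-sample left-to-right hidden
    Markov model with per-gap transition matrices regularized toward the
    ergodic model. Also provides structure-preserving permutation testing
    for false-discovery-rate estimation, region calling and
    classification against gene annotation, enrichment statistics,
    commonality summaries across individuals, and a synthetic-data
    simulator with ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
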