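Package: splicescore
Title: Splice-Site Scoring with a Small 1D-CNN and Score-Aware Spliced Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns donor/acceptor splice-site signals from a genome and its
    gene annotation with a small two-layer one-dimensional convolutional
    neural network, calibrates raw network scores to integer empirical
    log-odds by score binning, precomputes splice scores for every GT/AG
    dinucleotide on both strands of a genome, and consumes the scores inside
    a reference spliced-alignment dynamic program with an intron state.
    Includes a synthetic genome simulator with planted splice grammar,
    ROC/restricted-AUC and junction-accuracy evaluation, broom-style tidiers
    and ggplot2 autoplot methods, and a command-line entry point covering the
    full simulate/train/scan/align workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
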