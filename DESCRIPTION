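Package: pantriad
Title: Pan-Transcriptome Analysis of Polyploid Homoeolog Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative transcriptomics across a polyploid
    pan-genome: core/shell/cloud orthogroup classification, homoeolog
    (triad and n-let) expression-bias classification against ternary
    centroids with stable/dynamic partitioning, tissue-specificity (tau),
    tandem-duplicate expression balance and cross-cultivar chain
    conservation, k-mer gene-coverage scans for introgression candidates,
    coeliac-disease epitope expression scoring with degenerate motif
    search, and co-expression module eigengene divergence and metamodule
    detection. Includes a synthetic-data generator that emulates the
    statistical structure of a hexaploid wheat pan-transcriptome with
    planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    Rcpp,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    cluster,
    withr
Config/testthat/edition: 3
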