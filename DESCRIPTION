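Package: exoscreen
Title: Design and Analysis of Barcoded Exosomal miRNA CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for pooled CRISPR screens that read out extracellular
    vesicle (EV) release through barcoded exosomal microRNA (bEXOmiR)
    reporters. Covers design of error-tolerant 15-nt barcode sets under
    GC-content, homopolymer, restriction-site and pairwise Hamming-distance
    constraints; assembly of miR-30-backbone hairpin constructs and
    sgRNA-bEXOmiR cloning cassettes; mismatch-tolerant deconvolution of
    sequencing reads into element-level count matrices; maximum-likelihood
    gene effect-size estimation against a negative-control null with
    permutation p-values and replicate combination; NanoString-style miRNA
    normalization utilities; and a synthetic-screen generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
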