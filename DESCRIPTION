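Package: hdzipr
Title: Genome-Wide Characterization of HD-Zip Transcription-Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully scriptable pipeline for genome-wide
    characterization of the plant HD-Zip (homeodomain plus leucine-zipper)
    transcription-factor family: profile-based identification of dual-domain
    family members with empirical E-values, neighbor-joining subfamily
    classification with bootstrap support cross-checked against
    domain-architecture rules, exon-intron structure statistics, ZOOPS
    expectation-maximization motif discovery, tandem and segmental
    duplication calling from chained flank alignments, promoter cis-element
    scanning with exact-binomial subfamily enrichment, FPKM expression
    classification with fold-change calling, and qPCR analysis via
    2^-ddCt with Duncan's multiple range test. A synthetic-data module
    generates genomes, proteomes, promoters, expression matrices and Ct
    tables with planted ground truth so every stage can be validated
    against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    digest
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
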