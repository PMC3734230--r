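Package: mtcompare
Title: Comparative Analysis of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of circular annotated plant
    mitochondrial genomes: repeat landscape detection and direct/inverted
    classification by seed-and-extend self-comparison, chloroplast-derived
    (MTPT) segment scanning and classification, a tRNA origin census with
    Dollo/loss-only gain-loss placement on a species tree, circular
    gene-order extraction with syntenic-cluster counting and conserved-cluster
    matrices, masked shared-sequence matrices, conserved-gene concatenation
    with p-distance neighbor-joining phylogeny, and a synthetic plant-mtDNA
    generator with full truth tables so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    dplyr,
    ggplot2,
    IRanges,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
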