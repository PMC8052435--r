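Package: anchorsmith
Title: Anchored Hybrid Enrichment Locus Design and Sequence Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing anchored hybrid enrichment (AHE) probe sets
    and processing the resulting capture data, upstream of tree inference.
    Implements conserved-target discovery by spaced k-mer scanning of genome
    assemblies against transcript references, recruitment of capture reads to
    loci with seed-and-confirm matching, quasi-de novo extension assembly
    into flanking regions, IUPAC ambiguity consensus calling under an exact
    binomial sequencing-error model, alignment-free 20-mer orthology
    clustering, automated alignment trimming/masking/filtering, uniform probe
    tiling at a requested coverage depth, mtCOI barcode species assignment,
    and a seeded simulator of divergent taxon panels with full truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
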