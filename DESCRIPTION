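Package: bhlhscan
Title: Genome-Wide Survey and Phylogenetic Classification of bHLH
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for identifying and classifying basic helix-loop-helix
    (bHLH) transcription factors in draft genomes. Provides translated
    local-alignment search of genome scaffolds, domain detection with
    conserved-site validation and basic/helix1/loop/helix2 region
    segmentation, internally implemented neighbor-joining and Fitch
    parsimony tree inference with column-bootstrap supports, a
    monophyly-based ortholog-assignment cascade, exon-intron structure
    mapping onto the domain, a seeded synthetic-data generator with
    complete truth tables, and a packaged reference catalog of the brown
    planthopper bHLH repertoire.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    methods,
    purrr,
    Rcpp,
    readr,
    rtracklayer,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
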