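Package: orthochannel
Title: Ion Channel Gene Complements by Alignment, Synteny and Loss Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for establishing the complement of an ion channel (or any)
    gene family in a focal genome from pairwise BLAT alignments and gene
    annotations: hit-significance scoring and reciprocal top-hit orthology
    calls, flanking-gene synteny verification with phylogenetic linking
    through intermediate species, Dollo-parsimony placement of gene losses on
    a species tree, gene-model completeness assessment by alignment-block
    subtraction, and reconciliation of microarray and in situ hybridization
    differential-expression calls. Includes a ground-truthed synthetic-data
    generator for end-to-end validation, and packaged worked-example tables
    for the zebra finch sodium/calcium/chloride channel complement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
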