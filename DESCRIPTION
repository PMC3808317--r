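Package: mirpare
Title: Small RNA miRNA Discovery, Differential Expression and Degradome
    Target Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style pipeline for plant small-RNA sequencing
    studies: adapter cleaning and collapsing of raw reads, annotation
    against non-coding RNA and known miRNA databases, discovery of novel
    miRNAs by excising and folding candidate stem-loop precursors
    (Zuker-style minimum-free-energy dynamic programming with
    miRNA-star duplex criteria), Audic-Claverie differential expression
    between two libraries, and degradome (PARE) based validation of
    miRNA cleavage targets with t-plots and category I/II/III calls.
    Includes a seeded synthetic-data generator so every stage can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
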