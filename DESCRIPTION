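Package: offrisk
Title: Transcriptome-Based CRISPR Off-Target Detection and Phenotypic Risk Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CRISPR-Cas9 on- and off-target candidate sites directly on
    assembled transcript sequences (no reference genome required), screens
    transcripts for downregulation in edited versus wild-type RNA-seq samples
    by TPM ratio or by an external differential-expression table, intersects
    the two to call deleterious off-target sites, aggregates them to gene
    ontology terms, and scores per-term phenotypic risk with an exponentially
    mismatch-weighted index (the D-index). Each score is calibrated against a
    seeded permutation null, and a false-detection-rate procedure based on
    freshly shuffled datasets estimates the expected number of true calls.
    Includes seeded synthetic-data generators with planted ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
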