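Package: proteopipe
Title: Downstream Analysis Pipeline for Label-Free DIA Proteomic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for the downstream analysis of
    quantitative protein-by-sample intensity matrices from label-free
    data-independent-acquisition (DIA) proteomics of matched tumor cohorts,
    with a focus on formalin-fixed paraffin-embedded (FFPE) material and its
    heavy intensity-dependent missingness. Provides valid-value filtering,
    invariant-protein median normalization, unpaired Mann-Whitney differential
    expression with Benjamini-Hochberg adjustment and volcano classification,
    stochastic consensus non-negative matrix factorization (NMF) with
    cophenetic-correlation and dispersion rank selection and Kim-Park feature
    relevance scoring, phenotype-permutation gene set enrichment analysis on
    GMT collections, intersection-based candidate nomination, immunoblot
    validation statistics, and a seeded synthetic-cohort generator with known
    ground truth (planted differential expression, planted sample clusters,
    per-sample depth offsets, and MNAR plus MAR dropout) for end-to-end
    testing without access to raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
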