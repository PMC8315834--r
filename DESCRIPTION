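Package: phenonet
Title: Disease Phenotyping with Higher-Order Diagnosis Features and
    Generalized Disease Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven identification of complex disease phenotypes from
    hospital claims. Mines higher-order diagnosis features (frequent itemsets
    filtered by support and a minimum-information-difference-to-prior measure)
    from binary diagnosis matrices, fits a multi-target naive Bayes model
    whose coefficients are weights of evidence in decibans, quantifies
    synergistic and redundant disease interactions through the lift of a
    feature against its lower-order decomposition, builds a generalized
    disease network by maximum-entropy backboning of the coefficient
    similarity matrix with Louvain clustering, and compares matched
    index-disease phenotype cohorts with deciban effect sizes and G-tests.
    Ships a seeded synthetic-claims generator with planted latent phenotypes
    and beyond-pairwise dependencies so the whole pipeline is exercisable
    without access to real claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
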