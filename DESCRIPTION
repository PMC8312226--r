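Package: micronet
Title: Compositional Co-Occurrence Networks, Keystone Taxa and Attack
    Tolerance for Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for 16S-derived taxon count tables:
    compositionally robust co-occurrence network inference (SparCC basis
    correlations with Dirichlet resampling, iterative strong-pair exclusion
    and permutation pseudo-p-values), signed network construction and
    topology summaries, keystone-taxon scoring (eigenvector centrality,
    ubiquity, relative abundance), attack-tolerance curves measuring
    connectivity loss under random or betweenness-directed node removal,
    rarefied alpha/beta diversity with PERMANOVA and nonparametric group
    tests, negative-binomial Wald log2-fold-change differential abundance,
    Dirichlet Monte-Carlo clr Spearman correlation of taxa with continuous
    covariates such as antibody titres, copy-number-based functional
    (gene and pathway) prediction, and qPCR 2^-ddCt fold changes. Ships a
    synthetic-data generator with a planted keystone hub so the whole
    pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phangorn,
    picante,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
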