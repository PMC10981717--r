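Package: milknet
Title: Integrated Network Analysis of the Milk Proteome and Peptidome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers association networks from combined protein and
    endogenous-peptide abundance profiles of human milk. Provides a
    synthetic-data generator with planted partial-correlation structure and
    in-silico proteolysis, MaxQuant-dialect ingestion with prevalence
    filtering and left-censored (MNAR) imputation, shrinkage Gaussian
    graphical modeling, empirical-Bayes local false discovery rate edge
    calibration, Leiden community detection under the Constant Potts Model,
    hypergeometric GO overrepresentation, and peptidome-specific analyses
    (peptide ladders, exoproteolytic trimming, protease cleavage
    specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    MASS,
    rlang,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
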