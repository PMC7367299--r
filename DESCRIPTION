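Package: phylobrt
Title: Phylogenetically Informed Boosted Regression Trees for Comparative
    Trait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks species traits against phylogenetic eigenvectors as
    correlates of a continuous species-sensitivity proxy using boosted
    regression trees. Provides majority-rule consensus trees with averaged
    branch lengths, patristic distance matrices, principal coordinate
    analysis with cumulative-variance eigenvector selection, typed
    trait-table assembly (including residual testes mass and migration
    distance derivations), a least-squares gradient-boosting engine with
    bagging, cross-validated tree-count selection, relative-influence
    variable importance, partial dependence and pairwise interaction
    screening, and a deviance partition of the fitted model into trait and
    phylogeny components. A synthetic-data module simulates Yule trees,
    Brownian-motion and Mk traits, and subtype-discretised responses so the
    full analysis is exercisable end to end.
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
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
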