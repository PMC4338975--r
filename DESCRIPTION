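Package: phypairs
Title: Mixed-Model Analysis of Phylogenetically Paired Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of phylogenetically paired experimental designs, in which
    replicated measurements are taken on pairs of closely related species (for
    example one native and one invasive species per pair). Provides restricted
    maximum likelihood (REML) fitting of a linear mixed model with random
    effects for pair and for species within pair, inducing a two-layer
    compound-symmetry covariance structure; small-sample inference for the
    origin effect via the Kenward-Roger adjusted F-test, an exact balanced-design
    F-test, and a parametric bootstrap; a phylogenetically explicit simulator
    (Yule trees with Brownian trait evolution generating correlated pair
    effects); and a simulation harness measuring Type I error and power of
    competing analysis models over a grid of variance components.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    lmerTest,
    pbkrtest,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
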