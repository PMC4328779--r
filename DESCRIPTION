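Package: phylosong
Title: Phylogenetic Comparative Analysis of Birdsong Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative analysis of acoustic traits on
    a time-calibrated phylogeny, built around the leaf-warbler (Phylloscopidae)
    song system. Derives verse-level song measurements into per-taxon trait
    tables, quantifies phylogenetic signal (Blomberg's K with a
    contrast-variance randomization test, Pagel's lambda by profile maximum
    likelihood), selects among five continuous-trait evolution models
    (Brownian motion, Ornstein-Uhlenbeck, early burst, lambda, white noise)
    by AICc, and estimates trait-predictor relationships via raw correlations,
    phylogenetically independent contrasts, backward-stepwise linear models
    and phylogenetic generalized least squares. Includes a synthetic-data
    generator with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    nlme,
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
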