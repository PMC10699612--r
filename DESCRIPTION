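Package: rsfsa
Title: Random-Subset Feature Selection for Presence-Background Habitat Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building presence-background species distribution
    models over imagery-derived predictor rasters, centred on a cross-validated
    random-subset feature-selection algorithm (RSFSA-CV). Derives seven
    families of vegetation-index predictors (raw indices, multitemporal
    differences, preferred-range percent cover, grey-level co-occurrence
    texture, and their combinations) from multiband scenes, fits an
    l1-penalized maximum-entropy-style model, screens thousands of
    decorrelated feature subsets with AUC and AICc criteria across three
    staged rounds, ranks variables by weighted permutation importance and
    frequency, and assembles max-TSS-calibrated binary consensus ensembles
    with core and semi-core habitat maps, areal extents and land-cover
    composition summaries. Includes a seeded synthetic-scene generator so the
    whole pipeline is testable without proprietary imagery or occurrence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
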