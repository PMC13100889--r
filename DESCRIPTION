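Package: basinsdm
Title: Multi-Resolution Species Distribution Models on Nested Hydrological Basins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and evaluates ensemble species distribution models for
    freshwater fish on hierarchically nested hydrological basin units at
    several spatial resolutions, and quantifies how the choice of resolution
    affects predictive skill (true skill statistic), permutation variable
    importance, and predicted versus observed range size. Includes a
    synthetic-landscape simulator (nested basin hierarchies, spatially
    autocorrelated predictors, virtual species, spatially biased detection
    effort) so the entire workflow runs at desk scale, target-group
    pseudoabsence sampling, geographically independent holdouts on
    macro-basins, a nine-member model ensemble weighted by cross-validated
    TSS, and max-TSS binarisation of occurrence probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    splines,
    MASS,
    mgcv,
    nnet,
    rpart,
    ranger,
    xgboost,
    glmnet,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
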