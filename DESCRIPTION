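Package: gutdev
Title: Longitudinal Infant Gut Microbiome Development Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal analysis of the developing
    infant gut microbiome from count tables: Dirichlet-multinomial mixture
    (DMM) community typing with Laplace-approximation model selection,
    community-state transition and developmental-phase modelling,
    microbiota-age regression forests with microbiota-for-age Z (MAZ)
    scoring, permutation-based screening of dynamic covariates on
    ordinations, per-taxon covariate association models on
    variance-stabilised relative abundances, KEGG-module step-completeness
    calling with per-species attribution, and 1:1 matched case-control
    stability analysis by conditional logistic regression. Includes a seeded
    synthetic-cohort generator that plants known community types, covariate
    effects, maturation signal and case-control structure so every stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    vegan,
    randomForest,
    sandwich,
    withr,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
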