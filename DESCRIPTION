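Package: zsustain
Title: Z-Score Event-Based Subtype and Stage Inference for Regional Brain Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based disease-progression analysis in preclinical
    Alzheimer's disease cohorts. Regional brain volumes are adjusted for
    healthy covariate trends estimated in amyloid-negative controls and
    converted to abnormality z-scores; a z-score event-based mixture model
    infers latent atrophy subtypes (distinct event orderings) and stages,
    with MCMC sampling of sequence uncertainty, cross-validation information
    criterion (CVIC) model selection, and maximum-likelihood subtype and stage
    assignment including a sub-threshold subtype zero. Includes
    cross-sectional group comparisons (Pearson chi-square, ANOVA from summary
    statistics, Mann-Whitney U, Holm-Bonferroni adjustment), a random-intercept
    linear mixed model of longitudinal cognitive decline, and a synthetic
    cohort generator with ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
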