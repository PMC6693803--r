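Package: handwashr
Title: Country, Regional and Global Estimates of Handwashing with Soap
    After Potential Faecal Contact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-stage estimation pipeline that converts sparse national
    survey data on the presence of designated handwashing facilities into
    country, regional and global estimates of the prevalence of handwashing
    with soap (HWWS) after potential faecal contact. Stage one fits a
    logit-scale linear multilevel model to survey proportions of households
    with a designated handwashing facility and extrapolates to countries
    without data, with Monte-Carlo and prediction-interval uncertainty.
    Stage two estimates the prevalence ratio of observed HWWS by facility
    presence from pooled structured-observation datasets (modified Poisson
    with cluster-robust standard errors) and pools observed HWWS proportions
    across high-income-country studies by DerSimonian-Laird random-effects
    meta-analysis. Stage three combines facility presence with conditional
    prevalences into population-weighted HWWS estimates with delta-method
    uncertainty propagation. Includes synthetic-data generators emulating the
    sparsity and clustering structure of the source data, leave-one-out
    cross-validation, and sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
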