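Package: bpjoint
Title: Joint Multilevel Modelling of Systolic and Diastolic Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maximum-likelihood estimation of a bivariate two-level linear
    mixed model for systolic and diastolic blood pressure measured on women
    nested in households, with household-level and woman-level 2x2 covariance
    components. Includes variance partition coefficients, cross-outcome
    residual correlations, Wald tests of equality of a risk factor's effect
    across the two outcomes, likelihood-ratio and information-criterion model
    comparison, hypertension classification and descriptive tabulation, a
    household-clustered synthetic data generator for survey-like cohorts, and
    regional prevalence choropleth mapping from GeoJSON geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
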