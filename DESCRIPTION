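Package: le8trends
Title: Life's Essential 8 Cardiovascular Health Scoring and Design-Based
    Trend Estimation for Serial Cross-Sectional Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the American Heart Association "Life's Essential 8"
    (LE8) cardiovascular-health scoring algorithm (eight 0-100 component
    scores and their mean), including Healthy Eating Index-2015 diet-quality
    scoring from 24-hour dietary recall component amounts; an analytic-sample
    exclusion cascade for NHANES-style examination surveys; design-based
    survey estimation with Taylor-linearized standard errors over strata and
    primary sampling units, weighted percentiles, direct age standardization,
    covariate-adjusted weighted trend regression with cluster-robust
    variance, and Rao-Scott corrected chi-square homogeneity tests; and a
    synthetic-cohort generator with known ground truth so the full pipeline
    is testable without external survey files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    foreign
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
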