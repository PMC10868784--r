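Package: attrclaims
Title: Case Finding for Transthyretin Amyloid Cardiomyopathy in Administrative Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for identifying potential transthyretin
    amyloid cardiomyopathy (ATTR-CM) cases in reimbursement claims shaped like
    the Brazilian public-health inpatient (SIH) and outpatient (SIA) systems.
    Provides a seeded synthetic claims generator with known latent disease
    classes, multi-pass blocking record linkage to rebuild patient journeys,
    an ICD-10/procedure rule cascade labelling reference and potential cases,
    supervised model selection (regularized logistic regression, support
    vector machine, gradient-boosted trees, random forest) that splits the
    potential pool into "like" and "non" cases, and descriptive epidemiology
    reports: classification proportions, prevalence, demographics, annual
    hospitalization rates, and per-patient-per-year resource utilization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    ggplot2,
    glmnet,
    e1071,
    xgboost,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
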