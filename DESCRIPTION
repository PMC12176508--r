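Package: oncophen
Title: EHR-Based Classification of Cancer Site and Metastatic Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational phenotyping of oncology cohorts from electronic
    health record (EHR) extracts. Assigns cancer site from coded ICD-10-CM
    diagnoses by three competing algorithms (all coded categories, the single
    majority category, and the two most frequent categories), classifies
    metastatic status by six tri-state classifiers (diagnosis codes, a
    rule-based clinical-text engine with assertion classification, tumor
    registry stage, treatment-plan goals, incurable-indication medications,
    and phase I trial encounters) with an adjudication rule over the two
    primary classifiers, and compares classifiers with Cohen's and Fleiss'
    kappa and standardized-mean-difference covariate balance. Includes a
    synthetic-cohort generator with known ground truth and a nested-marginal
    reconstruction that turns published per-method positive counts into full
    contingency tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
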