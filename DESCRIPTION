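Package: oedprog
Title: Feature-Count Prognostic Models for Oral Epithelial Dysplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of multi-rater histological feature panels for oral
    epithelial dysplasia (OED). Provides majority-rule consensus feature
    calling, chance-corrected inter-rater agreement statistics (Fleiss-type
    kappa and Gwet's AC1), six-point and two-point feature-count prognostic
    scores, Kaplan-Meier risk estimation and Cox proportional-hazards
    regression with Efron's correction for tied times, AUROC-based model
    evaluation with the DeLong test for correlated AUCs, and a calibrated
    synthetic-cohort generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
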