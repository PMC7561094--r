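Package: surgrisk
Title: Perioperative Mortality Risk Scores and Prognostic Model Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes per-patient predicted 30-day postoperative mortality from
    published perioperative risk models (SORT, P-POSSUM, SRS) expressed as
    configurable generalized-linear scoring specifications, represents the
    6-category subjective clinical risk scale, and fits a combined
    subjective-plus-SORT logistic model. Ships a full prognostic-validation
    suite (calibration with Hosmer-Lemeshow, ROC/AUROC for continuous and
    ordinal predictors, DeLong's test for correlated ROC curves, continuous net
    reclassification improvement, decision-curve analysis, and bootstrap
    optimism correction), a synthetic perioperative cohort generator for
    end-to-end testing, and a study pipeline orchestrating exclusions, scoring
    and the inferential analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
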