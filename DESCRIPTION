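Package: bpbenefit
Title: Individualized Benefit and Harm Prediction for Intensive Blood
    Pressure Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation and validation of counterfactual risk models for
    intensive versus standard blood pressure treatment in two-arm
    randomized trials. Fits Cox proportional-hazards models with
    treatment-by-covariate interactions by elastic-net penalized partial
    likelihood (with repeated internal cross-validation) or by backwards
    AIC selection, converts fitted models into 5-year absolute
    risk-difference scores (absolute risk reduction in cardiovascular
    events, absolute risk increase in serious adverse events), evaluates
    discrimination (Harrell's C) and calibration (decile calibration
    table and the Greenwood-Nam-D'Agostino chi-square test), recalibrates
    baselines for external cohorts, and reports tertile subgroup tables
    with NNT/NNH. Includes the published SPRINT/ACCORD-BP score
    coefficient fixtures and a synthetic randomized-trial generator with
    known treatment-effect heterogeneity for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
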