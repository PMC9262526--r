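Package: catmcid
Title: Clinical Interpretation of Computerized Adaptive Syndrome Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and clinical-interpretation pipeline for a
    computerized adaptive test (CAT) of six traditional-Chinese-medicine
    syndrome elements in functional dyspepsia. Provides a multidimensional
    graded-response CAT engine (D-optimal item selection, maximum a
    posteriori scoring), min-max score standardization, ROC/Youden
    diagnostic-threshold calibration with kappa and McNemar agreement
    against clinician diagnoses, anchor- and distribution-based estimation
    of minimal clinically important differences (MCID) on a quality-of-life
    instrument, responder classification, and logistic-regression linkage
    of syndrome-score changes to MCID-defined clinical outcomes, together
    with a synthetic cohort generator that emulates the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
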