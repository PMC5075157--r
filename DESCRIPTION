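Package: impactpe
Title: Claims-Based IMPACT Risk Stratification for Pulmonary Embolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the IMPACT ("In-hospital Mortality for PulmonAry
    embolism using Claims daTa") logistic prediction rule and a complete,
    testable validation pipeline for it on administrative claims data:
    a synthetic claims generator with known ground truth, index-event
    cohort construction with enrollment and transfer exclusions,
    ICD-9-CM comorbidity ascertainment from configurable code sets,
    absolute-risk scoring with low/high classification at the 1.5 percent
    threshold, in-hospital and 30-day endpoint ascertainment, and
    prognostic-accuracy evaluation (sensitivity, specificity, predictive
    values with Wilson confidence intervals, rank-based AUC with DeLong
    variance, risk-stratified calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lubridate,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
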