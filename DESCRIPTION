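Package: ntcpval
Title: External Validation and Updating of NTCP Models for Xerostomia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the external validation, updating and clinical-utility
    assessment of logistic normal tissue complication probability (NTCP)
    models for radiation-induced xerostomia. Provides dose-volume histogram
    handling with EQD2 conversion under the linear-quadratic model,
    registry-style cohort assembly with inclusion/exclusion tracking and
    follow-up selection, the LIPP xerostomia model and its update levels
    (intercept shift, recalibration, revision), calibration and
    discrimination metrics (calibration slope and intercept,
    Hosmer-Lemeshow, Brier score, AUC), a closed testing procedure for
    choosing among update levels, decision-curve analysis, and a synthetic
    registry generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
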