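Package: pelandmark
Title: Sequentially Updated Preeclampsia Risk Prediction from Routine
    Antenatal Visits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-style dynamic prediction of preeclampsia in
    nulliparous women from routinely collected antenatal care data.
    Fits non-preeclamptic population mean trajectories of blood
    pressure, weight, hemoglobin and symphysis-fundal height with
    mixed-effects models, summarises each woman's departure from those
    curves as standardized level, trend and curvature u-scores, and
    combines them with early-pregnancy covariates and categorical
    glucose/proteinuria markers in per-landmark logistic risk models
    evaluated by AUC with DeLong confidence intervals and sensitivity
    at a fixed false-positive rate. Includes a seeded synthetic-cohort
    generator calibrated to published cohort descriptives, so the full
    pipeline is testable without access to the original registry data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    jsonlite,
    lme4,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
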