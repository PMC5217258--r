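Package: akiread
Title: Acute Kidney Injury Episode Detection and Unplanned Readmission
    Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and stages acute kidney injury (AKI) episodes from
    serial serum creatinine using KDIGO-based e-alert criteria with a
    rolling baseline, assembles a hospital-discharge cohort with renal,
    comorbidity and admission-context predictors, and develops logistic
    prediction models for unplanned readmission or death with backward
    stepwise selection, bootstrap optimism correction, decision curve
    analysis and reclassification metrics. Includes a synthetic cohort
    generator that emulates linked laboratory and hospital-episode data
    with ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
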