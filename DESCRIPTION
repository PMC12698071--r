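Package: acucost
Title: Cost Accrual and Budget-Impact Modelling of Acute Care Use in Oncology
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for costing oncology service utilisation against Medicare
    fee schedules (three-component MPFS payments plus 106%-of-ASP drug
    pricing), accruing per-patient daily costs over a 180-day
    systemic-therapy window, comparing acute-care-use (ACU) and non-ACU
    cohorts with confidence intervals and hypothesis tests, projecting the
    budget impact of deploying an ACU risk-prediction model, and running
    deterministic break-even sensitivity analyses.  A seeded synthetic
    claims-data generator emulates a two-group oncology cohort so the whole
    pipeline is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
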