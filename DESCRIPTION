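Package: biaval
Title: Validation of Budget-Impact Projections Against Payer Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating health technology assessment (HTA)
    budget-impact projections against realized payer reimbursement claims.
    Reads and normalizes monthly claims ledgers from hospital and outpatient
    reimbursement channels, interpolates HTA Year-1/Year-5 patient
    projections, summarizes observed utilization (median monthly patients,
    unit cost per patient-month), builds counterfactual projected-cost
    scenarios, and quantifies forecast error through observed-to-projected
    ratios, absolute expenditure gaps, Laspeyres-style volume/price
    decomposition, and log-log elasticity regression with channel and year
    stratification. Includes a synthetic claims generator with logistic
    uptake, expansion shocks and controllable projection bias, and a packaged
    reference table from the 2019 Bulgarian HTA cohort (NHIF claims,
    2020-2025) used as a worked validation example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
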