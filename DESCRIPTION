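Package: acscea
Title: Markov Cohort Cost-Effectiveness Modelling of Person-Centred Care
    for Acute Coronary Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model of disease progression after
    an acute coronary syndrome event, comparing person-centred care with usual
    care in patients under 65. Accumulates discounted costs and
    quality-adjusted life years under three costing perspectives (direct
    healthcare costs, plus sick-leave indirect costs, plus mortality-related
    productivity losses valued by the human-capital method), and reports
    incremental cost-effectiveness ratios with dominance semantics and net
    monetary benefit. Includes deterministic sensitivity analysis (discount
    scenarios, one-way sweeps, bisection threshold search), probabilistic
    sensitivity analysis with moment-matched beta and log-normal parameter
    distributions (cost-effectiveness plane and acceptability curve), and
    estimators that derive the model parameters from patient-level
    register-like records, together with a synthetic register-data generator
    used both for testing the estimators and as an individual-level
    microsimulation cross-check of the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
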