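Package: cascadecea
Title: Evaluation of Conditional Financial Incentives on the HIV Care Continuum
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis pipeline for evaluating conditional financial
    incentive programs aimed at improving HIV care continuum outcomes
    (engagement in care, retention in care, viral suppression) among persons
    living with HIV. Provides a seeded synthetic-cohort generator calibrated to
    a Southern US clinic population, eligibility screening predicates,
    windowed classification of care-continuum outcomes from dated viral-load
    tests, conditional-incentive ledger accounting with exact cent arithmetic,
    scoring of baseline psychosocial instruments (incentive acceptability,
    AUDIT-C, PHQ-9, CASE adherence, internalized HIV stigma), longitudinal
    time-trend and baseline-correlates logistic regression with
    cluster-robust standard errors, and a micro-costing cost, cost-utility and
    cost-threshold analysis (infections averted, QALYs saved, net cost per
    QALY, cost-saving and cost-effectiveness thresholds).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    sandwich,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
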