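Package: dbtriage
Title: Selective Addition of Breast Tomosynthesis to Mammography Screening
    by AI Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates screening policies that add a digital breast
    tomosynthesis (DBT) examination to digital mammography (DM) screening
    only for women whose examination scores above a threshold on an AI
    cancer-detection risk score. Builds a deterministic evaluation cohort
    from published joint recall counts of a paired double-reading trial,
    simulates stochastic synthetic cohorts with the same statistical
    structure, applies combination and DBT-precedence triage workflows
    across score thresholds, and reports detected, extra and missed
    cancers, false positives, positive predictive value, exact
    Clopper-Pearson binomial confidence intervals, per-stratum
    cancer-characteristic breakdowns, population organ dose, and relative
    reading-time change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
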