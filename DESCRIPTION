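Package: anccov
Title: Antenatal Care Coverage and Retention Analysis for Longitudinal
    Pregnancy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates antenatal care (ANC) coverage indicators (at least
    one, four, and eight visits) with Agresti-Coull binomial confidence
    intervals from longitudinal pregnancy-cohort data, resolves gestational
    age through an evidence hierarchy (early ultrasound, last menstrual
    period, fundal height, maternal recall), computes sequential and
    cumulative retention across gestational-age visit windows, runs
    deterministic loss-to-follow-up sensitivity scenarios, and ships a
    seeded synthetic-cohort simulator with closed-form implied truth for
    validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
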