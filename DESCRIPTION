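Package: fallrisk
Title: Prognostic Validity Analysis for a Multifactorial Fall Risk Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating the prognostic validity of a 0-100
    multifactorial Fall Risk Score (FRS) in longitudinal cohorts of older
    adults. Implements weighted risk-factor scoring, cohort eligibility
    filtering and (T1, T2) observation pairing, normalization of reported
    falls to weekly rates, FRS-indexed running-average smoothing, candidate
    regression model fitting with RMSE-based selection, inversion of the
    fitted fall-rate model into horizon-specific risk thresholds,
    distribution-based minimal clinically important differences with
    bootstrap confidence intervals, subgroup analyses, and a seeded
    synthetic cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
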