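Package: pneumorule
Title: Clinical Decision Rules for Ruling Out Radiographic Pneumonia in
    Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating clinical decision rules that
    rule out pneumonia visible on chest X-ray among primary-care patients
    with a suspected lower respiratory tract infection. Dichotomizes vital
    signs at standard cut-offs, evaluates Boolean sign combinations on 2x2
    contingency tables, computes diagnostic performance panels (sensitivity,
    specificity, predictive values, likelihood ratios, AUROC) with exact and
    log-method confidence intervals, fits logistic regression models with
    AIC backward selection, compares paired rules (sensitivity differences,
    negative-likelihood-ratio ratios), measures inter-rater agreement
    (Cohen's kappa, specific agreement), converts likelihood ratios into
    post-test probabilities, and simulates seeded synthetic cohorts with a
    known generating process for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
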