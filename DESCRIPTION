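Package: nustriage
Title: Thyroid Nodule Ultrasound Risk Scores and FNA Triage Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Applies five rule-based thyroid nodule ultrasound risk-stratification
    systems (K-TIRADS, ATA 2015, AACE/ACE-AME, EU-TIRADS, ACR TI-RADS) to a common
    sonographic feature lexicon and evaluates their fine-needle-aspiration (FNA)
    triage performance. Includes cytology dichotomization under the SIAPEC-IAP and
    British Thyroid Association schemes, cohort eligibility filtering, expected
    versus observed FNA sparing accounting, diagnostic metrics (sensitivity,
    specificity, PPV, NPV with Wald confidence intervals), ordinal ROC/AUC with
    Hanley-McNeil intervals, Cohen's kappa with Landis-Koch bands, a seeded
    synthetic cohort generator, and packaged count fixtures for regression testing
    of published summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
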