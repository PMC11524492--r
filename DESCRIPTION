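Package: sepsiswear
Title: Wearable Vital-Sign Analysis and Advanced-Sepsis Detection for
    Pediatric ICU Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous wearable vital-sign monitoring of
    children with sepsis in intensive care: simulation of a monitored cohort
    driven by a latent severity process; signal-quality filtering; pSOFA,
    Goldstein SIRS and modified pediatric early-warning-score (MPEWS) scoring
    from editable age-band threshold tables; windowed feature engineering;
    ridge-regression detection of advanced sepsis (pSOFA total > 8) with
    iterated cross-validation and false-positive-rate-matched comparison
    against clinician documentation; detection lead-time analysis; and
    manual-versus-wearable agreement statistics (Pearson correlation, mean
    absolute error, repeated-measures Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
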