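Package: oliguard
Title: Early Warning of Severe Oliguric Acute Kidney Injury from Urine Output Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for early detection of severe (KDIGO stage 2/3)
    oliguric acute kidney injury in intensive-care patients from irregularly
    charted urine-output and serum-creatinine streams. Provides a reproducible
    synthetic ICU cohort generator, hourly resampling and imputation of
    nurse-charted urine volumes and laboratory creatinine,
    ideal-body-weight normalisation, KDIGO urine-output and creatinine staging
    with composite oliguric-AKI episode detection, inclusion/exclusion
    filtering, 12-hour sliding-window sample construction with a 24-hour
    prediction horizon, two model families (multi-feature logistic regression
    and a parallel-branch one-dimensional convolutional network), and ROC
    operating-point evaluation with likelihood ratios and Hanley-McNeil
    standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
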