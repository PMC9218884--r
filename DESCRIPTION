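Package: asthmawarn
Title: Timeliness and False-Positive Analysis for Asthma Hospital-Visit
    Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Backtesting toolkit for longitudinal clinical risk models that
    predict asthma hospital visits (emergency-department visits and inpatient
    stays with a principal asthma diagnosis). Provides a synthetic
    electronic-health-record cohort simulator with a plantable prodromal
    utilization signal, ICD-9/10 asthma case-finding and visit-classification
    rules, as-of-date feature extraction with strict temporal hygiene, a
    pluggable annual risk model with a top-decile classification cutoff,
    a daily-resolution advance-warning lead-time (k) scan with warning
    survival curves, and a surrogate-outcome analysis of false-positive
    predictions (systemic-corticosteroid orders, exacerbation-coded visits,
    later hospital visits, and external-registry visits).
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
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
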