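Package: dyadhealth
Title: Non-Categorical Child Health Indicators and Maternal Outcomes from
    Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds mother-child dyads from linked administrative health
    records (registry, physician claims, drug dispensings, hospital
    abstracts), classifies children by two non-categorical health
    indicators (High Service Use, based on medication-days coverage in a
    sliding 365-day window and age-specific 95th-percentile physician
    visit cut-offs; and Diagnosis of a major and/or chronic condition via
    a configurable diagnosis-to-ADG mapping), and compares maternal health
    and service-use outcomes across the resulting four-level grouping with
    pooled-SD Cohen's d effect sizes and linear and logistic regression
    including the Nagelkerke pseudo R-squared. Includes a seeded,
    calibrated synthetic-data generator emulating linked provincial
    claims streams with known ground truth for end-to-end testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
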