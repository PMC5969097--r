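Package: prefiv
Title: Physician-Preference Instrumental Variables for Prescribing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-effectiveness analyses of prescribing
    decisions in primary-care records when treated and comparator patients
    differ systematically at baseline (healthy-user confounding). Implements
    cohort construction from prescription-level tables (new-user,
    intention-to-treat design with washout and registration windows),
    multi-horizon binary outcome windows with censoring, chained-equation
    multiple imputation with Rubin pooling, propensity-score nearest-neighbour
    matching, physician prescribing-preference proxy instruments built from
    each prescriber's recent first prescriptions, two-stage least-squares
    estimation with physician-clustered standard errors, instrument-strength
    and bias-component diagnostics, and a synthetic electronic-medical-record
    generator so the whole pipeline can be exercised and validated without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    data.table,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils,
    withr
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
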