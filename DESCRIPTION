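Package: doacaudit
Title: Guideline-Concordance Auditing of Direct-Acting Oral Anticoagulant Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits dosing of direct-acting oral anticoagulants (dabigatran,
    rivaroxaban, apixaban) in non-valvular atrial fibrillation against
    label-based renal and clinical dose-reduction criteria. Builds the study
    cohort from EHR-like tables with a reproducible exclusion cascade,
    derives patient-level clinical scores (MDRD eGFR, BMI, CHA2DS2-VASc,
    Elixhauser count), classifies received versus recommended doses
    (including the eight apixaban criteria groups), aggregates concordance
    rates by site and over time, fits multivariable logistic models of
    guideline-discordant dosing, and analyses dose-switch patterns among
    excluded rivaroxaban recipients. Ships a seeded synthetic-EHR generator
    with injectable, covariate-dependent discordance for testing and
    methods development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    jsonlite,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
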