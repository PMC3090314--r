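Package: diabrx
Title: Phenotyping Treated Type 2 Diabetes from Pharmacy Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies patients with treated diabetes from longitudinal
    drug-reimbursement records that carry no diagnosis codes, using yearly
    counts of ATC A10 (hypoglycemic agent) deliveries, and distinguishes
    type 2 from type 1 diabetes via oral-agent exposure and a data-driven
    age threshold for the switch to insulin-only treatment. Provides
    gold-standard-free interval estimates of sensitivity, specificity and
    predictive values over a plausible range of the true type-2 proportion,
    annual and age/sex-stratified treated prevalence with direct
    age-standardization, trend summaries, and projection by Brown's double
    exponential smoothing. Includes a ground-truth-labelled synthetic claims
    generator so the full pipeline is testable without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
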