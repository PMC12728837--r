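Package: cpregister
Title: Chronic Pain Registers, Consultation Costs, and Demographic
    Inequalities from Coded Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a chronic-pain (CP) disease register from coded
    primary-care prescription and diagnosis events using a tiered case
    definition: four or more prescription-only analgesics in the previous
    twelve months, or a diagnosis of a condition strongly associated with
    pain (tier 1), or a less strongly associated condition (tier 2)
    together with at least three analgesic prescriptions, with
    dual-indication exclusions (for example antiepileptics in patients
    with an epilepsy code) and exclusion of cancer pain. Provides
    comparator long-term-condition registers, consultation-rate and
    consultation-cost summaries under a provider-by-mode unit-cost
    schedule, multivariable logistic-regression modelling of demographic
    inequalities in register membership, a seeded synthetic electronic
    health record generator for end-to-end validation, and a pipeline
    orchestrator with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
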