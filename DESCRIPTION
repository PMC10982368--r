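Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance analysis pipeline for FDA Adverse
    Event Reporting System (FAERS) quarterly extracts, built around the safety
    screen of the beta-3 adrenergic agonist mirabegron: tolerant ingestion of
    the dollar-delimited ASCII tables, FDA-rule case deduplication, drug-name
    matching and primary-suspect/healthcare-professional cohort curation,
    MedDRA preferred-term to system-organ-class mapping, reporting odds ratio
    (ROR) and Bayesian confidence propagation neural network (BCPNN)
    information-component screening with dual signal criteria, descriptive
    case characterization, time-to-onset summaries, stratified subgroup
    re-screening, and a synthetic FAERS-like data generator with planted
    signals of known relative risk for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
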