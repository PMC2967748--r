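Package: ademiner
Title: Mining Multi-Item Adverse Drug Event Associations from Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects multi-item adverse drug event (ADE) associations in
    spontaneous reporting system (SRS) data with a typed, constrained
    Apriori frequent-itemset miner. Rules are restricted to the
    drugs-in-antecedent / events-in-consequent form and screened by report
    support and the relative reporting ratio (RR) rather than confidence.
    Includes readers for a simple transactions format and an AERS-style
    '$'-delimited quarterly ASCII dialect, deterministic drug-name cleanup
    with table-driven brand-to-generic mapping, corpus summary statistics,
    a synthetic SRS corpus generator with planted ground-truth associations
    for validation, and an end-to-end command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
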