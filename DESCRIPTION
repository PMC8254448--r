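Package: stewardaudit
Title: Antimicrobial Stewardship Audits from EMR Prescription-Indication Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the quality of in-hospital antibiotic use from
    electronic medical record (EMR) extracts in which every systemic
    antibiotic (ATC class J01) prescription carries a mandatory registered
    indication. The package derives each admission's empiric regimen via a
    24-hour snapshot rule, applies reproducible inclusion/exclusion criteria
    with CONSORT-style flowchart accounting, classifies regimens against a
    structured guideline table as first choice (A), second choice (B) or
    discordant (C), and quantifies indication-registration accuracy through a
    stratified chart-review validation workflow. A synthetic-data generator
    with full ground truth makes every pipeline stage testable without
    access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
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
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
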