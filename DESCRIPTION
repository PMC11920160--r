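Package: agranuvigil
Title: Pharmacovigilance Signal Detection for Drug-Induced Agranulocytosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for disproportionality analysis of
    non-chemotherapy drug-induced agranulocytosis in FAERS-style
    spontaneous adverse-event report data. Covers generation of synthetic
    FAERS quarterly bundles with planted drug-event associations,
    ingestion with case-version deduplication and delete-list filtering,
    cohort construction with ATC-based chemotherapy exclusion, reporting
    odds ratio (ROR) signal detection, three-tier risk classification,
    time-to-onset analysis stratified by demographics, and mortality-trend
    analysis with exact binomial confidence intervals and chi-square test
    batteries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
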