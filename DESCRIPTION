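Package: vcurate
Title: ACMG/AMP Variant Classification Engine and Curation Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline library and command-line toolkit for clinical germline
    variant curation. Implements the 28 ACMG/AMP evidence criteria with
    modifiable evidence strengths, the default rules for combining pathogenic
    and benign criteria into a five-tier classification, a reviewed-curation
    workflow state machine with immutable content-addressed snapshots,
    structured capture and aggregation of functional and case/segregation
    evidence with a PHI guard, a fixture-backed variant resolver with
    MANE-Select-aware display titles, and deterministic exports (evaluation
    summaries, ClinVar-submission-compatible TSV, and a SEPIO-aligned
    interpretation JSON document with strict round-trip parsing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    digest,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
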