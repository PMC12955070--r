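Package: raredq
Title: Data Quality Assessment for Rare Disease EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses the quality of electronic health record data on rare
    diseases. Parses an Alpha-ID-SE-style terminology to derive tracer
    diagnoses, reads case data from PAS-style CSV exports or MII-CDS-style
    FHIR resources (NDJSON or a paged FHIR REST endpoint), computes 13
    counting parameters and 7 normalized indicators covering completeness,
    plausibility and uniqueness, compares two datasets from the same source
    via per-parameter loss statistics, and writes k-anonymized two-sheet
    quality reports. Includes a deterministic synthetic-fixture generator
    with a planted-issue ledger for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
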