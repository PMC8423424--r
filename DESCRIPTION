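Package: omopetl
Title: Multi-Source EHR to OMOP CDM Transformation and Evaluation at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms a linked three-source electronic health record bundle
    (primary care, hospitalisation, mortality) into a subset of the OMOP
    Common Data Model (CDM) v5.2 and evaluates the transformation.
    Includes a synthetic source-data generator with planted,
    manifest-tracked data-quality defects; a vocabulary store resolving
    source codes to standard concepts, including two-hop drug mapping
    chains and wide-to-long entity-field maps; an ETL engine building
    person, observation-period, visit, clinical-event and drug-era tables
    with a complete exclusion ledger; code-list phenotyping executable
    against both the raw and the CDM representation; and evaluation
    reports covering vocabulary coverage, source-versus-CDM cohort
    concordance, clinical-covariate agreement, and data-quality checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
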