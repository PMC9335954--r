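Package: phenocart
Title: Structured Point-of-Care Phenotype Capture with the Human Phenotype Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structured deep phenotyping at the point of care:
    parse OBO-format ontologies such as the Human Phenotype Ontology into an
    indexed directed acyclic graph, search terms with autocomplete-style
    ranking, assemble per-patient annotation carts with negation flags and
    free-text comments, persist version-tagged append-only phenotype records
    as canonical JSON, and render them as RTF clinical-note tables, TSV, or
    Phenopacket-style JSON.  A dictionary-based concept extractor
    (Aho-Corasick) together with reproducible copy-paste corruption operators
    and an information-content gene ranker demonstrates how free-text term
    entry loses phenotype terms and degrades downstream phenotype-driven
    gene prioritization, compared with structured capture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
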