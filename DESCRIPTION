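Package: trialpubs
Title: Linking Registered Clinical Studies to Their Result Publications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Surveillance of results reporting for registered clinical
    studies. Parses ClinicalTrials.gov study records (API v2 JSON and
    legacy XML) and PubMed EFetch article records, selects a
    condition-specific study cohort by keyword, discovers trial-article
    links through two structured routes (registry result references and
    PubMed secondary identifiers), filters misclassified registry
    references by publication date, scores interventions by their
    per-phase trial counts, ranks publications with a configurable
    attention score, and emits prioritized publication lists and
    aggregate surveillance tables. Includes a seeded synthetic-corpus
    generator with ground-truth annotations so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
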