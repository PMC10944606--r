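Package: designminer
Title: Rule-Based Extraction and Classification of Epidemiological Study
    Designs from PubMed Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects, standardizes and classifies epidemiological study
    designs (cohort, case-control, randomised controlled trial, systematic
    review, meta-analysis, ...) reported in PubMed/MEDLINE abstracts using a
    dictionary of design terms and a small set of syntactic anchor rules.
    Extracted mentions are unified to one representative design per abstract,
    split into a lower-level design plus descriptive attributes, classified
    into five high-level nodes and aligned with the hierarchy of scientific
    evidence. Includes abstract-level precision/recall/F1 evaluation against
    gold annotations, a gold-annotated synthetic abstract generator for
    end-to-end testing without downloads, frequency/trend analytics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringr,
    tibble,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
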