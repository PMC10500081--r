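Package: picopipe
Title: Two-Step PICO Extraction from Randomized Controlled Trial Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step pipeline for extracting Population, Intervention,
    Comparison/Control and Outcome (PICO) elements from randomized
    controlled trial abstracts: sentences are first classified into the
    rhetorical sections background, methods, results and conclusions, and a
    BIO named-entity tagger is then applied to the title and the methods
    sentences, where the large majority of unique PICO mentions occur.
    Includes readers and writers for MEDLINE-style text, a PubMed XML
    subset, CoNLL token/tag files and JSON standoff annotations; a
    deterministic synthetic-corpus generator for end-to-end testing; a
    linear-chain structured-perceptron tagger with Viterbi decoding under a
    hard BIO transition mask; token-level, entity-level exact and partial
    match evaluation with micro-averaging; confusion matrices; Cohen's
    kappa inter-annotator agreement; document-level cross-validation; and a
    section-coverage analysis of where PICO mentions fall in an abstract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
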