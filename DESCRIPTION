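Package: conceptlit
Title: Concept-Based Literature Tagging and Search for Biocuration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A single-node concept-based literature tagging and retrieval
    toolkit supporting model-organism biocuration workflows. Parses
    MEDLINE/PubMed XML into article tibbles and maintains a versioned,
    reversed-PMID-keyed article store with incremental updates; compiles
    stemmed, case-split gazetteers from OBO ontologies and gene tables;
    tags titles, abstracts and MeSH headings with ontology concepts,
    organism names, gene mentions and mutation patterns; builds an
    inverted index and answers ontology-expanded, gene-synonym-expanded
    queries with facet counts, chainable filters and TF-IDF relevance
    ranking; and records curator interactions to decorate results with
    read-by and annotation-aspect indicators. Includes a deterministic
    fixture generator that plants ground-truth mentions so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
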