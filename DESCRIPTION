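Package: phenomine
Title: Ontology-Based Text Mining of Gene-Phenotype Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts gene-phenotype associations from literature by
    dictionary-based named entity recognition against a phenotype ontology
    and a gene lexicon, scoring sentence-level co-occurrences with
    ontology-propagated normalized pointwise mutual information (NPMI).
    The resulting phenotype profiles support candidate disease-gene
    prioritization through Resnik semantic similarity with best-match-average
    aggregation, evaluated by ROC AUC. Includes an OBO flat-file parser with
    subsumption closure and equivalence merging, a rule-based sentence
    splitter and tagger, and a synthetic-data generator that plants
    gene-phenotype co-mentions at controlled strength so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
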