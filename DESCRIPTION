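Package: ppitriage
Title: Triage of Protein-Protein Interaction Articles from Medline Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Document-level classification of Medline abstracts for
    protein-protein interaction (PPI) relevance. Detects gene and protein
    names with a statistical Priority Model, extracts word features
    (n-grams, character substrings, MeSH descriptor subphrases) and
    syntactic features (dependency relations with gene-name
    anonymization), induces higher-order conjunction features from loss
    gradients on misclassified documents, and trains a large-margin
    linear classifier under the modified Huber loss with data-derived
    regularization. Includes ranked-retrieval and binary-classification
    evaluation (accuracy, specificity, sensitivity, F1, Matthews
    correlation, average precision, interpolated precision-recall area,
    precision at rank n), a reproducible synthetic-corpus generator for
    end-to-end testing, and readers and writers for Medline tagged
    records, label tables, dependency parses, and SVMlight-style sparse
    vectors.
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
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
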