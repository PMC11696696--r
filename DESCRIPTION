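Package: crisprstack
Title: Doublet Stack Encoding and Contextual Sequence Models for CRISPR-Cas9 Off-Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts CRISPR-Cas9 off-target cleavage activity from sgRNA-DNA
    sequence pairs alone. Aligned 23-bp guide/target duplexes are tokenized by
    doublet stack encoding (overlapping two-base windows combining the guide and
    target dinucleotides, a 256-token vocabulary), embedded either contextually
    through a from-scratch transformer-encoder stack or through a static token
    embedding, and classified with a bidirectional LSTM head. Includes the full
    evaluation protocol for imbalanced off-target data (ROC-AUC and
    precision-recall AUC with explicit tie handling, stratified single-split and
    k-fold validation, and leave-one-sgRNA-out cross-validation with minimum
    positive-count guide grouping), positional doublet-frequency analysis, and a
    synthetic sgRNA-DNA pair generator with a known mismatch-driven label model
    so every component is testable without external data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
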