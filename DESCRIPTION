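Package: circpot
Title: Circular RNA Potential Classification from Primary Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a protein-coding gene or long noncoding RNA has
    a circular RNA (circRNA) isoform, and whether a circRNA is expressed in
    stem cells, from primary sequence alone. Transcripts are encoded as a
    178-dimensional feature vector (basic sequence composition, hashed
    neighborhood-pair graph-kernel features, conservation summaries and
    repeat/ORF/variant annotations), classified by five-fold cross-validation
    random-forest ensembles, and scored by rank aggregation: raw scores are
    converted to fractiles within each fold's validation score distribution,
    averaged, and calibrated against a table of empirical false positive
    rates on negative data. Includes a synthetic-data generator with tunable
    class signal so the whole pipeline is testable without genome downloads,
    and a command-line interface for the train/predict workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    ranger,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
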