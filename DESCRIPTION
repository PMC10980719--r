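Package: memlin
Title: Gene-Expression-Memory-Based Cell Lineage Inference for scRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts small-to-medium cell lineages (clones related over a few
    divisions) directly from single-cell RNA-seq count matrices, without genetic
    barcoding, by exploiting heritable gene expression ("memory") genes.
    Provides depth normalization and 10x-style matrix I/O, CV-squared-versus-mean
    gene selection, a repeated iterative Ward-clustering predictor that scores
    every cell pair with a co-clustering confidence level, memory-gene calling
    and categorization against lineage annotations, pair-level evaluation
    (precision, sensitivity, false positive rate, AUC) against ground truth,
    and a lineage-structured count simulator so the whole pipeline is testable
    without external data.
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
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
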