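Package: dcsignature
Title: Random-Forest Inflammation Signatures for Dendritic Cells with
    qRT-PCR Threshold Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives a transcriptional signature of dendritic-cell
    inflammation from a two-class expression compendium and validates it
    against qRT-PCR panels. Implements quality filtering on 3'/5' probe
    ratios, per-gene z-scoring, stratified train/test partitioning,
    bootstrap random-forest classification with Gini-importance backward
    elimination and an out-of-bag stopping rule, per-gene regulation
    directions, 2^-ddCt fold-change computation, direction-aware
    median-threshold scoring of stimuli with per-gene concordance, and a
    synthetic-data generator emulating the 115-array study design for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
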