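Package: p300ensemble
Title: Overlapped-Partitioning Ensemble LDA for P300 Spellers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying letters in a 6x6 row/column P300 speller from
    multichannel EEG. Implements the full event-related-potential processing chain
    (epoch extraction, baseline correction, moving-average smoothing, decimation,
    vectorization), linear discriminant analysis (LDA) weak learners trained on
    overlapped partitions of time-ordered training data, stepwise partial-F-test and
    principal-component dimension reduction, score aggregation across partitions and
    stimulus sequences, a p/q cross-validation evaluation scheme, the Wolpaw
    information transfer rate, and a synthetic speller-session simulator that emulates
    the oddball stimulus protocol so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
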