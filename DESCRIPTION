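Package: resistseq
Title: Cross-Cohort Gene Panel Discovery and Deep Ensemble Prediction of
    Chemoresistance from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers a chemoresistance gene panel from multi-cohort bulk
    RNA-seq TPM matrices and predicts platinum-chemotherapy resistance in
    high-grade serous ovarian carcinoma. Implements two-tier gene selection
    (cross-cohort Student's t-test intersection and per-cohort balanced
    bagging with a Mann-Whitney frequency filter), a five-fold deep ensemble
    of small fully connected networks trained with Adam on binary
    cross-entropy and selected fold-wise on a second cohort, sensitivity-
    prioritized decision thresholds, and a random-gene-panel null comparison.
    Includes a multi-cohort synthetic TPM generator with planted shared and
    cohort-specific differential genes so the whole workflow is testable
    without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
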