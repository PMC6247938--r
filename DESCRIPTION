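Package: bionertl
Title: Transfer Learning for Biomedical Named Entity Recognition with a
    Bi-LSTM-CRF Sequence Tagger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A character- and token-level bi-directional LSTM-CRF sequence
    tagger for biomedical named entity recognition, with support for transfer
    learning from a large, noisy silver-standard corpus to a small
    gold-standard corpus. Provides Brat standoff and CoNLL-style corpus
    input/output, tokenization and BIO/BIOES tag conversion, silver-corpus
    deduplication and blacklist filtering, per-example stochastic gradient
    training with gradient clipping, dropout and dev-set early stopping,
    layer-wise parameter transfer, entity-level exact-match evaluation
    (precision/recall/F1, macro averages, reduction in error, learning
    curves, error-set overlap, paired randomization tests), and a synthetic
    corpus generator that emulates clean gold-standard and noise-degraded
    silver-standard corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
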