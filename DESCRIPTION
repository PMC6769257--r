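Package: targpep
Title: Prediction of N-Terminal Targeting Peptides and Their Cleavage Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint classification of N-terminal protein sorting signals
    (signal peptides, mitochondrial and chloroplast transit peptides,
    thylakoid luminal transit peptides) and prediction of their cleavage
    sites with a bidirectional LSTM and a multi-attention mechanism in
    which four attention heads double as per-position cleavage-site
    predictors.  Includes BLOSUM62 sequence encoding, homology-aware
    nested cross-validation with a greedy identity-clustering stand-in,
    a one-hot multilayer-perceptron baseline, one-vs-rest classification
    and windowed cleavage-site metrics, confusion-matrix based correction
    of proteome-level class counts, attention and frequency sequence-logo
    matrices, and a generator of synthetic proteins with planted
    targeting-peptide grammars for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
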