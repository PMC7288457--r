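Package: m6acnn
Title: Convolutional Prediction of N6-Methyladenosine Sites in 51-nt RNA Windows
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies N6-methyladenosine (m6A) sites in fixed-length 51-nt
    RNA windows with a small two-block one-dimensional convolutional neural
    network trained on one-hot encoded sequence. Provides FASTA/TSV loaders
    with strict sequence validation, a declarative layer specification with
    an exact output-shape calculus, a self-contained training engine (valid
    convolution, ELU, group normalization, max pooling, dropout, SGD with
    momentum, L2 regularization, early stopping with checkpointing), a
    10-fold train/validation/test rotation protocol reporting sensitivity,
    specificity, accuracy, Matthews correlation and ROC/AUC, a hyperparameter
    grid search selected by validation loss, a planted-motif synthetic
    dataset generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
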