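Package: pssmTransformer
Title: Lightweight Transformer Classification of Adaptor Proteins from
    PSSM Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ultra-lightweight deep learning classifier that
    distinguishes adaptor proteins from non-adaptor proteins using
    position-specific scoring matrix (PSSM) profiles of arbitrary length.
    The model stacks three 1-D convolutional blocks with layer
    normalization, a single post-norm transformer encoder layer, global
    average pooling and a two-layer fully connected head, and is trained
    at batch size one with gradient accumulation, a class-weighted binary
    cross-entropy loss, Adam with validation-AUC plateau halving and early
    stopping, and stratified five-fold cross-validation. Includes a
    PSI-BLAST ASCII PSSM parser/writer, a synthetic profile generator for
    testing without external data, confusion-matrix/ROC/AUC/AUPRC/MCC
    evaluation, exact trainable-parameter accounting, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
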