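Package: sigdta
Title: Drug-Target Binding Affinity Prediction from k-mer Signature Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Alignment-free featurization of molecule SMILES strings and
    protein amino-acid sequences as square "signature images" built from
    max-normalized k-mer count vectors, together with a dual-branch
    convolutional neural network that regresses drug-target binding
    affinity from the image pair. Includes the full evaluation-metric
    suite used in binding-affinity benchmarking (mean squared error,
    concordance index, the rm2 external-validation metric, area under
    the precision-recall curve after threshold binarization), a reader
    for kinase benchmarks in the public DeepDTA text layout with the
    pKd transform and 5-fold-plus-test experiment plans, and a seeded
    synthetic-data generator so the whole pipeline is testable at desk
    scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
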