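Package: tcrbert
Title: Peptide:TCR Binding Prediction with a Transformer Encoder and
    Repertoire-Derived Decoys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating sequence-based predictors of
    peptide:T-cell-receptor (TCR) binding from CDR3-beta amino-acid
    sequences. The package covers the full modelling pipeline: curation of
    binder tables, Levenshtein-distance hierarchical clustering of peptides
    and TCRs, generation of negative decoys from healthy-donor reference
    repertoires with cluster-aware false-negative rejection and
    machine-learning outlier filtering, construction of a hypothetical
    peptide:TCR repertoire for masked-language-model pre-training, a
    dual-sequence transformer encoder trained with a focal-loss
    classification objective, and leakage-controlled grouped
    cross-validation with per-peptide AUROC and average precision. A seeded
    synthetic-data generator with planted peptide-motif binding rules makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    ranger,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
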