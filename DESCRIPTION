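Package: bictr
Title: Drug-Target Interaction Prediction with Bi-Clustering Tree
    Ensembles and Output Space Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTI) in bipartite
    drug-protein networks under cold-start conditions. The binary
    interaction matrix is first reconstructed with neighborhood-regularized
    logistic matrix factorization (NRLMF), replacing unlabeled entries by
    interaction probabilities while preserving verified interactions; an
    ensemble of extremely randomized bi-clustering trees is then trained on
    the reconstructed matrix. Includes cold-start cross-validation
    protocols for new drugs, new targets and both-new settings,
    micro-averaged AUROC/AUPR metrics, nested-CV hyperparameter tuning, a
    synthetic network generator with known ground truth, and plain-text
    matrix I/O compatible with the standard chemogenomics benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
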