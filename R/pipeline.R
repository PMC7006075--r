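#' Train the full BICTR model
#'
#' Pipeline: (1) fit NRLMF latent factors on the training network; (2)
#' reconstruct the interaction matrix, keeping observed interactions at 1
#' and replacing unlabeled entries by interaction probabilities; (3) train
#' the bi-clustering tree ensemble on the reconstructed matrix. The model
#' is fully inductive: nothing about future test instances is used, and
#' predictions depend only on the stored model and the test feature
#' vectors.
#'
#' With `skip_reconstruction = TRUE` the ensemble is trained on the raw
#' binary matrix instead — the eBICT baseline, useful as an ablation of
#' the reconstruction step.
#'
#' @param net training [dti_network()].
#' @param nrlmf_cfg an [nrlmf_config()].
#' @param ens_cfg an [ensemble_config()].
#' @param skip_reconstruction train trees on raw `Y` (eBICT ablation).
#' @return An object of class `bictr_model` with elements `latent`
#'   (`NULL` for eBICT), `ensemble`, `Yhat`, the training feature matrices
#'   and identifier lists.
#' @export
bictr_train <- function(net, nrlmf_cfg = nrlmf_config(),
                        ens_cfg = ensemble_config(),
                        skip_reconstruction = FALSE) {
  stopifnot(inherits(net, "dti_network"))
  latent <- NULL
  if (skip_reconstruction) {
    Yhat <- net$Y
  } else {
    latent <- nrlmf_fit(net, nrlmf_cfg)
    Yhat <- reconstruct(net, latent)
  }
  ensemble <- fit_ensemble(Yhat, net$X_d, net$X_p, ens_cfg)
  structure(
    list(latent = latent, ensemble = ensemble, Yhat = Yhat,
         X_d = net$X_d, X_p = net$X_p,
         drug_ids = net$drug_ids, protein_ids = net$protein_ids,
         skip_reconstruction = skip_reconstruction),
    class = "bictr_model")
}

#' @export
print.bictr_model <- function(x, ...) {
  cat(sprintf("<bictr_model> %s, %d drugs x %d proteins, %d trees\n",
              if (x$skip_reconstruction) "eBICT (no reconstruction)"
              else "BICTR (NRLMF reconstruction)",
              nrow(x$Yhat), ncol(x$Yhat), length(x$ensemble$trees)))
  invisible(x)
}

#' Predict interaction scores under a cold-start setting
#'
#' The three inductive settings of cold-start DTI prediction:
#' * `"td_lp"` — test drugs vs learned proteins: `drugs` is a feature
#'   matrix of new drugs, `proteins` an index vector into the training
#'   proteins (default: all of them).
#' * `"ld_tp"` — learned drugs vs test proteins: `drugs` is an index
#'   vector into the training drugs, `proteins` a feature matrix.
#' * `"td_tp"` — test drugs vs test proteins: both are feature matrices.
#'
#' Feature vectors of new instances must live in the training feature
#' space; for similarity-based features this means similarities to the
#' training instances, in the training column order.
#'
#' @param model a [bictr_train()] result.
#' @param drugs feature matrix or training-index vector (see setting).
#' @param proteins feature matrix or training-index vector (see setting).
#' @param setting one of `"td_lp"`, `"ld_tp"`, `"td_tp"`.
#' @return Score matrix (drugs x proteins) with entries in \[0, 1\].
#' @export
bictr_predict <- function(model, drugs = NULL, proteins = NULL,
                          setting = c("td_lp", "ld_tp", "td_tp")) {
  stopifnot(inherits(model, "bictr_model"))
  setting <- match.arg(setting)
  Xd <- switch(setting,
    td_lp = as_feature_matrix(drugs, "drugs"),
    ld_tp = learned_features(model$X_d, drugs, "drug"),
    td_tp = as_feature_matrix(drugs, "drugs"))
  Xp <- switch(setting,
    td_lp = learned_features(model$X_p, proteins, "protein"),
    ld_tp = as_feature_matrix(proteins, "proteins"),
    td_tp = as_feature_matrix(proteins, "proteins"))
  predict_ensemble(model$ensemble, Xd, Xp)
}

as_feature_matrix <- function(x, what) {
  if (is.null(x)) stop(sprintf("a feature matrix for new %s is required", what))
  as.matrix(x)
}

learned_features <- function(X, idx, what) {
  if (is.null(idx)) return(X)
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > nrow(X))) {
    stop(sprintf("learned %s index out of range 1..%d", what, nrow(X)))
  }
  X[idx, , drop = FALSE]
}

#' Save a BICTR model to a directory
#'
#' Writes the JSON tree ensemble, the latent factor matrices as delimited
#' text (absent for eBICT models), the reconstructed training matrix, the
#' training feature matrices, and the resolved configurations.
#'
#' @param model a [bictr_train()] result.
#' @param dir output directory, created if missing.
#' @export
write_bictr_model <- function(model, dir) {
  stopifnot(inherits(model, "bictr_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ensemble(model$ensemble, file.path(dir, "ensemble.json"))
  write_matrix_file(model$Yhat, file.path(dir, "yhat.txt"))
  write_matrix_file(model$X_d, file.path(dir, "drug_features.txt"))
  write_matrix_file(model$X_p, file.path(dir, "protein_features.txt"))
  meta <- list(skip_reconstruction = model$skip_reconstruction,
               drug_ids = model$drug_ids, protein_ids = model$protein_ids)
  if (!is.null(model$latent)) {
    write_matrix_file(model$latent$U, file.path(dir, "latent_U.txt"))
    write_matrix_file(model$latent$V, file.path(dir, "latent_V.txt"))
    meta$nrlmf_config <- unclass(model$latent$config)
    meta$objective_trace <- model$latent$objective_trace
  }
  jsonlite::write_json(meta, file.path(dir, "model.json"), digits = I(17),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(dir)
}

#' Load a BICTR model saved by [write_bictr_model()]
#'
#' @param dir model directory.
#' @return A `bictr_model`.
#' @export
read_bictr_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  ensemble <- read_ensemble(file.path(dir, "ensemble.json"))
  latent <- NULL
  if (!is.null(meta$nrlmf_config)) {
    cfg <- do.call(nrlmf_config, as.list(meta$nrlmf_config))
    latent <- structure(
      list(U = unname_matrix(read_matrix_file(file.path(dir, "latent_U.txt"))),
           V = unname_matrix(read_matrix_file(file.path(dir, "latent_V.txt"))),
           config = cfg, objective_trace = meta$objective_trace,
           graph_d = NULL, graph_p = NULL),
      class = "nrlmf_model")
  }
  structure(
    list(latent = latent, ensemble = ensemble,
         Yhat = read_matrix_file(file.path(dir, "yhat.txt")),
         X_d = read_matrix_file(file.path(dir, "drug_features.txt")),
         X_p = read_matrix_file(file.path(dir, "protein_features.txt")),
         drug_ids = meta$drug_ids, protein_ids = meta$protein_ids,
         skip_reconstruction = isTRUE(meta$skip_reconstruction)),
    class = "bictr_model")
}

unname_matrix <- function(M) {
  dimnames(M) <- NULL
  M
}
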