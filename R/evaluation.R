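#' Build cold-start cross-validation folds
#'
#' Folds are defined on network nodes, never on pairs, so that the whole
#' interaction profile of every test instance is absent from training:
#' * `"td_lp"` (test drugs, learned proteins): drugs are partitioned into
#'   `n_folds_drugs` near-equal folds.
#' * `"ld_tp"`: proteins are partitioned into `n_folds_proteins` folds.
#' * `"td_tp"`: drugs and proteins are partitioned into blocks and every
#'   (drug block, protein block) combination is one fold, e.g. 5 x 5 = 25
#'   folds; the training network excludes all rows of the drug block and
#'   all columns of the protein block.
#'
#' @param net a [dti_network()].
#' @param setting `"td_lp"`, `"ld_tp"` or `"td_tp"`.
#' @param n_folds_drugs folds over drugs (default 10; used by `td_lp` and
#'   `td_tp`).
#' @param n_folds_proteins folds over proteins (default 10 for `ld_tp`;
#'   `td_tp` conventionally uses 5 and 5).
#' @param seed partition seed.
#' @return An object of class `fold_plan`: list with `setting`, `folds`
#'   (each fold holds `test_drugs` and/or `test_proteins` index vectors),
#'   fold counts, and `seed`.
#' @export
make_folds <- function(net, setting = c("td_lp", "ld_tp", "td_tp"),
                       n_folds_drugs = 10, n_folds_proteins = 10, seed = 1) {
  stopifnot(inherits(net, "dti_network"))
  setting <- match.arg(setting)
  n_d <- nrow(net$Y)
  n_p <- ncol(net$Y)
  if (setting %in% c("td_lp", "td_tp") && n_folds_drugs > n_d) {
    stop(sprintf("n_folds_drugs = %d exceeds the %d drugs", n_folds_drugs, n_d))
  }
  if (setting %in% c("ld_tp", "td_tp") && n_folds_proteins > n_p) {
    stop(sprintf("n_folds_proteins = %d exceeds the %d proteins",
                 n_folds_proteins, n_p))
  }
  drug_blocks <- with_seed(derive_seed(seed, 40L),
                           partition_indices(n_d, n_folds_drugs))
  protein_blocks <- with_seed(derive_seed(seed, 41L),
                              partition_indices(n_p, n_folds_proteins))
  folds <- switch(setting,
    td_lp = lapply(drug_blocks, function(b) list(test_drugs = b)),
    ld_tp = lapply(protein_blocks, function(b) list(test_proteins = b)),
    td_tp = {
      out <- list()
      for (a in seq_along(drug_blocks)) {
        for (b in seq_along(protein_blocks)) {
          out[[length(out) + 1L]] <- list(test_drugs = drug_blocks[[a]],
                                          test_proteins = protein_blocks[[b]])
        }
      }
      out
    })
  structure(
    list(setting = setting, folds = folds,
         n_folds_drugs = as.integer(n_folds_drugs),
         n_folds_proteins = as.integer(n_folds_proteins),
         n_drugs = n_d, n_proteins = n_p, seed = as.integer(seed)),
    class = "fold_plan")
}

# Shuffle 1..n and cut into k near-equal slices (sizes differ by <= 1).
partition_indices <- function(n, k) {
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(idx, rep(seq_len(k), times = sizes))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> setting %s, %d folds over %d drugs x %d proteins\n",
              x$setting, length(x$folds), x$n_drugs, x$n_proteins))
  invisible(x)
}

#' Export / import a fold plan as JSON
#'
#' @param plan a [make_folds()] result.
#' @param path JSON file.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  jsonlite::write_json(unclass(plan), path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$folds <- lapply(x$folds, lapply, as.integer)
  class(x) <- "fold_plan"
  x
}

# Training/test feature views for one fold. Square similarity features are
# restricted to columns over training instances (the cold-start convention
# for similarity descriptors: a test instance is described by its
# similarity to the training set); rectangular features keep all columns.
fold_features <- function(X, train_idx, test_idx, n_instances) {
  similarity <- nrow(X) == ncol(X) && nrow(X) == n_instances
  keep <- if (similarity) train_idx else seq_len(ncol(X))
  list(train = X[train_idx, keep, drop = FALSE],
       test = X[test_idx, keep, drop = FALSE])
}

#' Run a cold-start cross-validated experiment
#'
#' For every fold: the network is restricted to its training instances, a
#' model is trained end-to-end (BICTR, or the eBICT ablation that skips
#' the reconstruction), the held-out block is predicted, and predictions
#' are pooled across folds. AUROC and AUPR are micro-averaged: computed
#' once on the pooled pair-level predictions of all kept test folds.
#' Per-fold metrics are also returned for paired comparisons. Folds whose
#' test labels are single-class are dropped with a warning.
#'
#' @param net a [dti_network()].
#' @param setting `"td_lp"`, `"ld_tp"` or `"td_tp"`.
#' @param method `"bictr"` or `"ebict"` (trees on the raw binary matrix).
#' @param n_folds_drugs,n_folds_proteins outer fold counts (defaults 10 for
#'   node settings; use 5 and 5 for `td_tp`).
#' @param nrlmf_cfg,ens_cfg component configurations; per-fold seeds are
#'   derived from `seed`.
#' @param seed experiment seed (folds and per-fold model seeds).
#' @param truth optional binary matrix of evaluation labels, same shape as
#'   `net$Y`; defaults to `net$Y`. Supplying the uncorrupted matrix of a
#'   synthetic network evaluates recovery of hidden positives.
#' @param fold_plan optional pre-built [make_folds()] plan (overrides the
#'   fold counts).
#' @return An object of class `bictr_eval`: list with pooled `auroc` and
#'   `aupr`, a `per_fold` data frame, the pooled `scores`/`labels`, and
#'   the resolved configurations.
#' @export
run_experiment <- function(net, setting = c("td_lp", "ld_tp", "td_tp"),
                           method = c("bictr", "ebict"),
                           n_folds_drugs = 10, n_folds_proteins = 10,
                           nrlmf_cfg = nrlmf_config(),
                           ens_cfg = ensemble_config(),
                           seed = 1, truth = NULL, fold_plan = NULL) {
  stopifnot(inherits(net, "dti_network"))
  setting <- match.arg(setting)
  method <- match.arg(method)
  if (is.null(truth)) truth <- net$Y
  stopifnot(all(dim(truth) == dim(net$Y)))
  if (is.null(fold_plan)) {
    fold_plan <- make_folds(net, setting, n_folds_drugs, n_folds_proteins,
                            seed = derive_seed(seed, 50L))
  } else {
    stopifnot(inherits(fold_plan, "fold_plan"),
              identical(fold_plan$setting, setting))
  }
  n_d <- nrow(net$Y)
  n_p <- ncol(net$Y)
  all_scores <- list()
  all_labels <- list()
  per_fold <- vector("list", length(fold_plan$folds))
  for (f in seq_along(fold_plan$folds)) {
    fold <- fold_plan$folds[[f]]
    test_d <- fold$test_drugs %||% integer(0)
    test_p <- fold$test_proteins %||% integer(0)
    train_d <- setdiff(seq_len(n_d), test_d)
    train_p <- setdiff(seq_len(n_p), test_p)
    fd <- fold_features(net$X_d, train_d, test_d, n_d)
    fp <- fold_features(net$X_p, train_p, test_p, n_p)
    train_net <- dti_network(net$Y[train_d, train_p, drop = FALSE],
                             fd$train, fp$train,
                             drug_ids = net$drug_ids[train_d],
                             protein_ids = net$protein_ids[train_p])
    ncfg <- nrlmf_cfg
    ecfg <- ens_cfg
    ncfg$seed <- derive_seed(seed, 100L + f)
    ecfg$seed <- derive_seed(seed, 200L + f)
    model <- bictr_train(train_net, ncfg, ecfg,
                         skip_reconstruction = (method == "ebict"))
    pred <- switch(setting,
      td_lp = bictr_predict(model, drugs = fd$test, setting = "td_lp"),
      ld_tp = bictr_predict(model, proteins = fp$test, setting = "ld_tp"),
      td_tp = bictr_predict(model, drugs = fd$test, proteins = fp$test,
                            setting = "td_tp"))
    lab <- switch(setting,
      td_lp = truth[test_d, train_p, drop = FALSE],
      ld_tp = truth[train_d, test_p, drop = FALSE],
      td_tp = truth[test_d, test_p, drop = FALSE])
    s <- as.vector(pred)
    l <- as.vector(lab)
    n_pos <- sum(l == 1)
    n_neg <- sum(l == 0)
    if (n_pos == 0 || n_neg == 0) {
      warning(sprintf(
        "fold %d dropped: test labels are single-class (%d positives, %d negatives)",
        f, n_pos, n_neg))
      per_fold[[f]] <- data.frame(fold = f, n_pairs = length(l),
                                  n_positives = n_pos, auroc = NA_real_,
                                  aupr = NA_real_, kept = FALSE)
      next
    }
    all_scores[[length(all_scores) + 1L]] <- s
    all_labels[[length(all_labels) + 1L]] <- l
    per_fold[[f]] <- data.frame(fold = f, n_pairs = length(l),
                                n_positives = n_pos, auroc = auroc(s, l),
                                aupr = aupr(s, l), kept = TRUE)
  }
  scores <- unlist(all_scores)
  labels <- unlist(all_labels)
  if (length(scores) == 0) stop("all folds were dropped; cannot evaluate")
  structure(
    list(setting = setting, method = method,
         auroc = auroc(scores, labels), aupr = aupr(scores, labels),
         per_fold = do.call(rbind, per_fold),
         scores = scores, labels = labels,
         fold_plan = fold_plan, nrlmf_cfg = nrlmf_cfg, ens_cfg = ens_cfg,
         seed = seed),
    class = "bictr_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bictr_eval <- function(x, ...) {
  cat(sprintf(
    "<bictr_eval> %s / %s: micro AUROC %.4f, micro AUPR %.4f (%d/%d folds kept)\n",
    toupper(x$method), x$setting, x$auroc, x$aupr,
    sum(x$per_fold$kept), nrow(x$per_fold)))
  invisible(x)
}
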