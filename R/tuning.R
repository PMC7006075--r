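#' Hyperparameter grid for NRLMF
#'
#' The conventional tuning grid for this model family: `lambda_d`,
#' `lambda_p`, `alpha`, `beta` and the learning rate each range over powers
#' of two `{2^-2, 2^-1, 2^0, 2^1}`, the neighbor count over `{3, 5, 10}`
#' and the latent dimension over `{50, 100}` — 4^5 * 3 * 2 = 6144
#' combinations in full.
#'
#' @param lambda_d,lambda_p,alpha,beta,learning_rate grid values.
#' @param n_neighbors,k grid values.
#' @return Data frame with one row per combination, columns named after
#'   [nrlmf_config()] arguments.
#' @export
nrlmf_grid <- function(lambda_d = 2^(-2:1), lambda_p = 2^(-2:1),
                       alpha = 2^(-2:1), beta = 2^(-2:1),
                       learning_rate = 2^(-2:1), n_neighbors = c(3, 5, 10),
                       k = c(50, 100)) {
  g <- expand.grid(lambda_d = lambda_d, lambda_p = lambda_p, alpha = alpha,
                   beta = beta, learning_rate = learning_rate,
                   n_neighbors = n_neighbors, k = k,
                   KEEP.OUT.ATTRS = FALSE)
  rownames(g) <- NULL
  g
}

#' Reproducibly sample a subset of a tuning grid
#'
#' The full grid is impractically large for routine runs; this draws
#' `n` rows without replacement, deterministically for a given seed.
#'
#' @param grid a data frame of parameter combinations.
#' @param n number of rows to keep.
#' @param seed sampling seed.
#' @export
grid_subset <- function(grid, n, seed = 1) {
  stopifnot(n >= 1)
  if (n >= nrow(grid)) return(grid)
  keep <- with_seed(derive_seed(seed, 60L), sort(sample.int(nrow(grid), n)))
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nested-CV hyperparameter tuning
#'
#' Inner cross-validation with the same cold-start setting as the outer
#' protocol: for every grid point, models are trained on the inner
#' training networks and scored on the inner test blocks; the point with
#' the best mean inner-fold metric wins, ties broken by grid order. Grid
#' points whose fit fails are recorded and skipped.
#'
#' @param net the (outer-fold training) [dti_network()].
#' @param grid data frame of parameter combinations; columns must be
#'   [nrlmf_config()] argument names (unlisted arguments keep the values
#'   of `base_cfg`).
#' @param setting cold-start setting for the inner folds.
#' @param inner_folds number of inner folds (block folds per axis for
#'   `td_tp`), default 5.
#' @param metric `"aupr"` (default) or `"auroc"`.
#' @param method `"bictr"` or `"ebict"`.
#' @param base_cfg baseline [nrlmf_config()] supplying unlisted fields.
#' @param ens_cfg [ensemble_config()] used for every grid point.
#' @param seed seed for inner folds and fits.
#' @param score_fun optional override for scoring a grid point: a
#'   `function(net, params, fold_plan)` returning a numeric vector of
#'   per-fold scores (larger is better). The default trains and evaluates
#'   the chosen method.
#' @return List with `best` (one-row data frame), `best_config` (the
#'   resolved [nrlmf_config()]), `scores` (mean inner metric per grid
#'   row, `NA` where the fit failed) and `failures`.
#' @export
nested_cv_tune <- function(net, grid, setting = c("td_lp", "ld_tp", "td_tp"),
                           inner_folds = 5, metric = c("aupr", "auroc"),
                           method = c("bictr", "ebict"),
                           base_cfg = nrlmf_config(),
                           ens_cfg = ensemble_config(), seed = 1,
                           score_fun = NULL) {
  setting <- match.arg(setting)
  metric <- match.arg(metric)
  method <- match.arg(method)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  plan <- make_folds(net, setting, n_folds_drugs = inner_folds,
                     n_folds_proteins = inner_folds,
                     seed = derive_seed(seed, 70L))
  if (is.null(score_fun)) {
    score_fun <- function(net, params, fold_plan) {
      cfg <- do.call(nrlmf_config,
                     modifyList(unclass(base_cfg), as.list(params)))
      res <- run_experiment(net, setting, method, nrlmf_cfg = cfg,
                            ens_cfg = ens_cfg, seed = derive_seed(seed, 71L),
                            fold_plan = fold_plan)
      res$per_fold[[metric]][res$per_fold$kept]
    }
  }
  scores <- rep(NA_real_, nrow(grid))
  failures <- character(0)
  if (nrow(grid) == 1L) {
    # singleton grid: nothing to compare, return it without inner fitting
    scores[1] <- NA_real_
  } else {
    for (i in seq_len(nrow(grid))) {
      params <- grid[i, , drop = FALSE]
      fold_scores <- tryCatch(
        score_fun(net, params, plan),
        error = function(e) {
          failures <<- c(failures, sprintf("grid row %d: %s", i,
                                           conditionMessage(e)))
          NULL
        })
      if (!is.null(fold_scores) && length(fold_scores) > 0) {
        scores[i] <- mean(fold_scores)
      }
    }
    if (all(is.na(scores))) {
      stop("every grid point failed during inner tuning")
    }
  }
  best_i <- if (all(is.na(scores))) 1L else which.max(scores)
  best <- grid[best_i, , drop = FALSE]
  rownames(best) <- NULL
  best_config <- do.call(nrlmf_config,
                         modifyList(unclass(base_cfg), as.list(best)))
  list(best = best, best_config = best_config, scores = scores,
       failures = failures, fold_plan = plan)
}
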