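#' Ensemble configuration for bi-clustering trees
#'
#' Each tree is grown on the full training matrix (no bootstrapping, in the
#' extremely-randomized-trees style): at every node a random subset of drug
#' features and of protein features is drawn, one uniform random threshold
#' is drawn strictly inside each feature's range within the node's block,
#' and the candidate with the largest variance reduction is kept. Trees are
#' grown unpruned until blocks are pure.
#'
#' @param n_trees number of trees, default 100.
#' @param n_row_candidates,n_col_candidates number of random drug/protein
#'   feature candidates per node; defaults to `ceiling(sqrt(F))` of the
#'   respective feature count at fit time when `NULL`.
#' @param min_samples_leaf minimum number of drug-protein pairs in a leaf.
#' @param exhaustive if `TRUE`, every feature is a candidate and all
#'   midpoints between consecutive distinct values are tried (deterministic
#'   best-split mode, mainly for verification; defeats the ERT
#'   randomization).
#' @param seed integer seed; per-tree streams are derived from it.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = 100, n_row_candidates = NULL,
                            n_col_candidates = NULL, min_samples_leaf = 1,
                            exhaustive = FALSE, seed = 1) {
  stopifnot(n_trees >= 1, min_samples_leaf >= 1)
  if (!is.null(n_row_candidates)) stopifnot(n_row_candidates >= 1)
  if (!is.null(n_col_candidates)) stopifnot(n_col_candidates >= 1)
  structure(
    list(n_trees = as.integer(n_trees),
         n_row_candidates = n_row_candidates,
         n_col_candidates = n_col_candidates,
         min_samples_leaf = as.integer(min_samples_leaf),
         exhaustive = isTRUE(exhaustive),
         seed = as.integer(seed)),
    class = "ensemble_config")
}

#' Node variance of a target block
#'
#' The impurity of a block is the sum over its outputs (columns for a row
#' split, rows for a column split) of the population variance times the
#' entry count — i.e. the total squared deviation of every entry from its
#' column's block mean. Both split orientations give the same number, and
#' the parent's value always upper-bounds the sum of its children's, so
#' variance reduction is nonnegative.
#'
#' @param M numeric matrix (a block of the target matrix).
#' @return Nonnegative scalar; 0 for a constant block.
#' @export
node_variance <- function(M) {
  M <- as.matrix(M)
  if (length(M) == 0) stop("empty block")
  cpp_node_variance(M)
}

#' Candidate split tests for a block
#'
#' Draws the random feature/threshold candidates a tree node would
#' consider, with their variance-reduction scores. Constant features within
#' the block are skipped. With `exhaustive = TRUE` all features and all
#' midpoint thresholds are returned instead.
#'
#' @param Yhat target matrix (reconstructed interaction matrix).
#' @param X_d,X_p drug and protein feature matrices.
#' @param rows,cols 1-based indices of the block.
#' @param config an [ensemble_config()].
#' @param seed RNG seed for the draws.
#' @return Data frame with columns `axis` (`"row"`/`"col"`), `feature`
#'   (1-based), `threshold`, `score`.
#' @export
candidate_splits <- function(Yhat, X_d, X_p, rows = seq_len(nrow(Yhat)),
                             cols = seq_len(ncol(Yhat)),
                             config = ensemble_config(), seed = config$seed) {
  cand_n <- resolve_candidates(config, ncol(X_d), ncol(X_p))
  df <- cpp_candidate_splits(as.matrix(Yhat), as.matrix(X_d), as.matrix(X_p),
                             as.integer(rows), as.integer(cols),
                             cand_n$row, cand_n$col, config$exhaustive,
                             as.double(derive_seed(seed, 20L)))
  df$axis <- c("row", "col")[df$axis]
  df
}

resolve_candidates <- function(config, F_d, F_p) {
  list(
    row = as.integer(if (is.null(config$n_row_candidates))
      ceiling(sqrt(F_d)) else min(config$n_row_candidates, F_d)),
    col = as.integer(if (is.null(config$n_col_candidates))
      ceiling(sqrt(F_p)) else min(config$n_col_candidates, F_p)))
}

#' Grow a single bi-clustering tree
#'
#' Recursively partitions the target matrix: a ROW split sends drugs with
#' `X_d[, feature] <= threshold` left, a COLUMN split does the same for
#' proteins, so each node's block is a submatrix and each leaf a bicluster.
#' Growth stops when a block is pure (total squared deviation below
#' `1e-12`), when no admissible candidate exists, or when a child would
#' fall below `min_samples_leaf` pairs. Leaves predict their block mean.
#'
#' @inheritParams candidate_splits
#' @param seed RNG seed for this tree.
#' @return An object of class `bictr_tree`: parallel node vectors `axis`
#'   (0 leaf / 1 row / 2 column), `feature`, `threshold`, `left`, `right`,
#'   `value`, plus per-leaf `leaf_rows` / `leaf_cols` index sets.
#' @export
grow_tree <- function(Yhat, X_d, X_p, config = ensemble_config(),
                      seed = config$seed) {
  Yhat <- as.matrix(Yhat)
  X_d <- as.matrix(X_d)
  X_p <- as.matrix(X_p)
  check_tree_inputs(Yhat, X_d, X_p)
  cand_n <- resolve_candidates(config, ncol(X_d), ncol(X_p))
  tree <- cpp_grow_tree(Yhat, X_d, X_p, cand_n$row, cand_n$col,
                        config$min_samples_leaf, config$exhaustive,
                        as.double(seed))
  class(tree) <- "bictr_tree"
  tree
}

check_tree_inputs <- function(Yhat, X_d, X_p) {
  if (length(Yhat) == 0) stop("empty training matrix")
  if (nrow(X_d) != nrow(Yhat)) {
    stop("drug feature matrix rows must match target matrix rows")
  }
  if (nrow(X_p) != ncol(Yhat)) {
    stop("protein feature matrix rows must match target matrix columns")
  }
  invisible(TRUE)
}

#' Fit an ensemble of bi-clustering trees
#'
#' Grows `config$n_trees` unpruned trees, each with an independent RNG
#' stream derived from `config$seed`; every tree sees the full training
#' matrix (randomization comes only from the feature/threshold draws).
#'
#' @inheritParams candidate_splits
#' @return An object of class `bictr_ensemble` with elements `trees`,
#'   `config`, `n_features_d`, `n_features_p`.
#' @export
fit_ensemble <- function(Yhat, X_d, X_p, config = ensemble_config()) {
  Yhat <- as.matrix(Yhat)
  X_d <- as.matrix(X_d)
  X_p <- as.matrix(X_p)
  check_tree_inputs(Yhat, X_d, X_p)
  cand_n <- resolve_candidates(config, ncol(X_d), ncol(X_p))
  seeds <- derive_seeds(config$seed, config$n_trees, key = 30L)
  trees <- lapply(seeds, function(s) {
    tr <- cpp_grow_tree(Yhat, X_d, X_p, cand_n$row, cand_n$col,
                        config$min_samples_leaf, config$exhaustive,
                        as.double(s))
    class(tr) <- "bictr_tree"
    tr
  })
  structure(
    list(trees = trees, config = config,
         n_features_d = ncol(X_d), n_features_p = ncol(X_p)),
    class = "bictr_ensemble")
}

#' @export
print.bictr_ensemble <- function(x, ...) {
  n_leaves <- vapply(x$trees, function(t) sum(t$axis == 0), numeric(1))
  cat(sprintf("<bictr_ensemble> %d trees, mean %.1f leaves/tree\n",
              length(x$trees), mean(n_leaves)))
  invisible(x)
}

#' Predict the interaction score of one drug-protein pair
#'
#' Traverses every tree (ROW nodes compare the drug feature vector, COLUMN
#' nodes the protein feature vector; "goes left" iff value <= threshold)
#' and averages the leaf values.
#'
#' @param ens a [fit_ensemble()] result.
#' @param x_d drug feature vector of length `n_features_d`.
#' @param x_p protein feature vector of length `n_features_p`.
#' @return Scalar score; lies in \[0, 1\] when trained on a reconstructed
#'   interaction matrix.
#' @export
predict_pair <- function(ens, x_d, x_p) {
  stopifnot(inherits(ens, "bictr_ensemble"))
  if (length(x_d) != ens$n_features_d) {
    stop(sprintf("drug feature vector has length %d, expected %d",
                 length(x_d), ens$n_features_d))
  }
  if (length(x_p) != ens$n_features_p) {
    stop(sprintf("protein feature vector has length %d, expected %d",
                 length(x_p), ens$n_features_p))
  }
  predict_ensemble(ens, matrix(x_d, 1), matrix(x_p, 1))[1, 1]
}

#' Predict a score matrix for drug x protein feature sets
#'
#' @param ens a [fit_ensemble()] result.
#' @param X_d_new,X_p_new feature matrices (one row per drug / protein).
#' @return Numeric matrix `nrow(X_d_new) x nrow(X_p_new)` of averaged tree
#'   predictions.
#' @export
predict_ensemble <- function(ens, X_d_new, X_p_new) {
  stopifnot(inherits(ens, "bictr_ensemble"))
  X_d_new <- as.matrix(X_d_new)
  X_p_new <- as.matrix(X_p_new)
  if (ncol(X_d_new) != ens$n_features_d || ncol(X_p_new) != ens$n_features_p) {
    stop("feature dimensions do not match the fitted ensemble")
  }
  cpp_predict_ensemble(lapply(ens$trees, unclass), X_d_new, X_p_new)
}

#' Extract the biclusters induced by a fitted tree
#'
#' The leaves of a bi-clustering tree partition the training matrix into
#' blocks: each leaf is a (drug subset) x (protein subset) bicluster, the
#' blocks are disjoint, and their union covers every training pair.
#'
#' @param tree a [grow_tree()] result (or one element of
#'   `ensemble$trees`).
#' @return List of `list(rows, cols)` index pairs, one per leaf.
#' @export
extract_biclusters <- function(tree) {
  if (!inherits(tree, "bictr_tree")) stop("not a fitted bi-clustering tree")
  leaves <- which(tree$axis == 0)
  lapply(leaves, function(i) {
    list(rows = tree$leaf_rows[[i]], cols = tree$leaf_cols[[i]])
  })
}

#' Save a tree ensemble as JSON
#'
#' The format stores, per tree, the parallel node arrays (`axis`,
#' `feature`, `threshold`, `left`, `right`, `value`) plus the per-leaf
#' index sets, with full numeric precision, so [read_ensemble()] restores
#' the model bit-exactly.
#'
#' @param ens a [fit_ensemble()] result.
#' @param path output file.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "bictr_ensemble"))
  payload <- list(
    format = "bictr_ensemble",
    version = 1L,
    n_features_d = ens$n_features_d,
    n_features_p = ens$n_features_p,
    config = unclass(ens$config),
    trees = lapply(ens$trees, unclass))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a tree ensemble saved by [write_ensemble()]
#'
#' @param path JSON file written by [write_ensemble()].
#' @return A `bictr_ensemble`.
#' @export
read_ensemble <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "bictr_ensemble")) {
    stop("not a bictr ensemble file: ", path)
  }
  cfg <- payload$config
  config <- ensemble_config(
    n_trees = cfg$n_trees, n_row_candidates = cfg$n_row_candidates,
    n_col_candidates = cfg$n_col_candidates,
    min_samples_leaf = cfg$min_samples_leaf, exhaustive = cfg$exhaustive,
    seed = cfg$seed)
  trees <- lapply(payload$trees, function(tr) {
    out <- list(
      axis = ivec_na(tr$axis),
      feature = ivec_na(tr$feature),
      threshold = dvec_na(tr$threshold),
      left = ivec_na(tr$left),
      right = ivec_na(tr$right),
      value = dvec_na(tr$value),
      leaf_rows = relist_leaves(tr$leaf_rows, length(tr$axis)),
      leaf_cols = relist_leaves(tr$leaf_cols, length(tr$axis)))
    class(out) <- "bictr_tree"
    out
  })
  structure(
    list(trees = trees, config = config,
         n_features_d = as.integer(payload$n_features_d),
         n_features_p = as.integer(payload$n_features_p)),
    class = "bictr_ensemble")
}

# JSON null (from NA) keeps vectors as lists on read; flatten back.
dvec_na <- function(x) {
  if (is.list(x)) vapply(x, function(v) if (is.null(v) || is.na(v)) NA_real_
                         else as.numeric(v), numeric(1))
  else as.numeric(x)
}

ivec_na <- function(x) {
  if (is.list(x)) vapply(x, function(v) if (is.null(v) || is.na(v)) NA_integer_
                         else as.integer(v), integer(1))
  else as.integer(x)
}

relist_leaves <- function(x, n) {
  if (is.null(x)) return(vector("list", n))
  out <- lapply(x, function(v) if (is.null(v)) NULL else as.integer(unlist(v)))
  length(out) <- n
  out
}
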