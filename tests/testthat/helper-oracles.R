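# Independent brute-force oracles used to verify the package's
# implementations. These deliberately use naive enumeration, never the
# code paths they check.

# ROC area by trapezoidal integration over all score thresholds.
auroc_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

# Average precision accumulated threshold by threshold, counting TP/FP by
# explicit subsetting; tied scores enter as one step.
aupr_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Direct double-loop block impurities in both split orientations.
sse_cols_oracle <- function(M) {
  tot <- 0
  for (j in seq_len(ncol(M))) {
    m <- mean(M[, j])
    for (i in seq_len(nrow(M))) tot <- tot + (M[i, j] - m)^2
  }
  tot
}

sse_rows_oracle <- function(M) sse_cols_oracle(t(M))

# Score one split the way the tree learner defines it: column-oriented
# impurity for ROW splits, row-oriented for COLUMN splits.
split_reduction_oracle <- function(Y, Xd, Xp, axis, feature, threshold) {
  if (axis == 1) {
    L <- Xd[, feature] <= threshold
    sse_cols_oracle(Y) - sse_cols_oracle(Y[L, , drop = FALSE]) -
      sse_cols_oracle(Y[!L, , drop = FALSE])
  } else {
    L <- Xp[, feature] <= threshold
    sse_rows_oracle(Y) - sse_rows_oracle(Y[, L, drop = FALSE]) -
      sse_rows_oracle(Y[, !L, drop = FALSE])
  }
}

# Exhaustive enumeration of every (axis, feature, midpoint) split.
best_split_oracle <- function(Y, Xd, Xp) {
  best <- -Inf
  for (f in seq_len(ncol(Xd))) {
    v <- sort(unique(Xd[, f]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      L <- Xd[, f] <= t
      if (!any(L) || all(L)) next
      best <- max(best, split_reduction_oracle(Y, Xd, Xp, 1, f, t))
    }
  }
  for (f in seq_len(ncol(Xp))) {
    v <- sort(unique(Xp[, f]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      L <- Xp[, f] <= t
      if (!any(L) || all(L)) next
      best <- max(best, split_reduction_oracle(Y, Xd, Xp, 2, f, t))
    }
  }
  best
}

# Walk a single tree in R, mirroring the documented traversal semantics.
traverse_oracle <- function(tree, xd, xp) {
  i <- 1L
  while (tree$axis[i] != 0L) {
    v <- if (tree$axis[i] == 1L) xd[tree$feature[i]] else xp[tree$feature[i]]
    i <- if (v <= tree$threshold[i]) tree$left[i] else tree$right[i]
  }
  tree$value[i]
}

# Negative Bernoulli log-likelihood of Y under the logistic link.
bernoulli_nll_oracle <- function(U, V, Y) {
  nll <- 0
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      p <- plogis(sum(U[i, ] * V[j, ]))
      nll <- nll - (Y[i, j] * log(p) + (1 - Y[i, j]) * log(1 - p))
    }
  }
  nll
}

# Small dense-ish network fixture with continuous similarity features.
make_toy_net <- function(n_d = 8, n_p = 6, density = 0.25, seed = 1) {
  generate_synthetic(n_d, n_p, rank = 2, density = density,
                     feature_noise = 0.05, seed = seed)$network
}

# Wrap a single tree as an ensemble so predict_ensemble() applies.
single_tree_ensemble <- function(tree, n_features_d, n_features_p) {
  structure(
    list(trees = list(tree), config = ensemble_config(n_trees = 1),
         n_features_d = n_features_d, n_features_p = n_features_p),
    class = "bictr_ensemble")
}
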