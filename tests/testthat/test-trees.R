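test_that("node_variance equals the double-loop impurity oracle", {
  expect_equal(node_variance(matrix(0.3, 2, 2)), 0)
  expect_equal(node_variance(matrix(c(0, 1), 2, 1)), 0.5)  # 2 entries x 0.25
  withr::with_seed(31, {
    for (rep in 1:10) {
      M <- matrix(runif(35), 7, 5)
      expect_equal(node_variance(M), sse_cols_oracle(M), tolerance = 1e-12)
    }
  })
  expect_error(node_variance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("candidate splits obey the ERT rule and score by variance reduction", {
  sim <- make_toy_net(10, 8, seed = 2)
  net <- sim
  m <- nrlmf_fit(net, nrlmf_config(k = 2, max_iters = 20))
  Yhat <- reconstruct(net, m)
  cfg <- ensemble_config(n_row_candidates = 4, n_col_candidates = 3)
  cs <- candidate_splits(Yhat, net$X_d, net$X_p, config = cfg, seed = 5)
  expect_lte(sum(cs$axis == "row"), 4)
  expect_lte(sum(cs$axis == "col"), 3)
  expect_true(all(cs$score >= 0))
  # thresholds strictly inside the block range of their feature
  for (i in seq_len(nrow(cs))) {
    X <- if (cs$axis[i] == "row") net$X_d else net$X_p
    v <- X[, cs$feature[i]]
    expect_gt(cs$threshold[i], min(v))
    expect_lt(cs$threshold[i], max(v))
  }
  # scores match the independent reduction oracle
  for (i in seq_len(nrow(cs))) {
    ax <- if (cs$axis[i] == "row") 1 else 2
    expect_equal(cs$score[i],
                 split_reduction_oracle(Yhat, net$X_d, net$X_p, ax,
                                        cs$feature[i], cs$threshold[i]),
                 tolerance = 1e-10)
  }
})

test_that("constant features yield no candidates", {
  Yhat <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2)
  Xd <- matrix(1, 2, 3)
  Xp <- matrix(2, 2, 2)
  cs <- candidate_splits(Yhat, Xd, Xp, config = ensemble_config(), seed = 1)
  expect_equal(nrow(cs), 0)
  # growing under all-constant features degenerates to a single leaf
  tr <- grow_tree(Yhat, Xd, Xp, ensemble_config(seed = 1))
  expect_equal(sum(tr$axis == 0), 1)
  expect_equal(tr$value[1], mean(Yhat))
})

test_that("a perfectly separating feature attains the full parent variance", {
  # rows 1:2 have target 0, rows 3:4 target 1; feature 1 separates them
  Yhat <- rbind(matrix(0, 2, 3), matrix(1, 2, 3))
  Xd <- cbind(c(0, 0, 1, 1), c(0.3, 0.6, 0.2, 0.9))
  Xp <- matrix(seq_len(6) / 7, 3, 2)
  cs <- candidate_splits(Yhat, Xd, Xp,
                         config = ensemble_config(exhaustive = TRUE), seed = 1)
  sep <- cs[cs$axis == "row" & cs$feature == 1, ]
  expect_equal(sep$score, rep(node_variance(Yhat), nrow(sep)))
})

test_that("grow_tree handles pure roots and hand-separable fixtures", {
  # constant target: single leaf
  tr <- grow_tree(matrix(0.5, 3, 4), matrix(rnorm(9), 3), matrix(rnorm(8), 4),
                  ensemble_config(seed = 2))
  expect_equal(tr$axis, 0L)
  expect_equal(tr$value, 0.5)

  # 4x4 checkerboard separable by one row and one column feature
  Yhat <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1),
                c(1, 1, 0, 0), c(1, 1, 0, 0))
  Xd <- matrix(c(0, 0, 1, 1), 4, 1)
  Xp <- matrix(c(0, 0, 1, 1), 4, 1)
  tr <- grow_tree(Yhat, Xd, Xp, ensemble_config(exhaustive = TRUE, seed = 3))
  expect_equal(sum(tr$axis == 0), 4)   # four pure leaves
  expect_equal(sum(tr$axis != 0), 3)   # root + two children
  leaves <- extract_biclusters(tr)
  vals <- vapply(leaves, function(b) unique(c(Yhat[b$rows, b$cols])),
                 numeric(1))
  expect_setequal(vals, c(0, 1, 1, 0))

  expect_error(grow_tree(matrix(numeric(0), 0, 0), matrix(0, 0, 1),
                         matrix(0, 0, 1)), "empty")
})

test_that("exhaustive split choice matches brute-force enumeration", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      Y <- matrix(runif(30), 6, 5)
      Xd <- matrix(rnorm(18), 6, 3)
      Xp <- matrix(rnorm(15), 5, 3)
      tr <- grow_tree(Y, Xd, Xp, ensemble_config(exhaustive = TRUE, seed = rep))
      chosen <- split_reduction_oracle(Y, Xd, Xp, tr$axis[1], tr$feature[1],
                                       tr$threshold[1])
      expect_equal(chosen, best_split_oracle(Y, Xd, Xp), tolerance = 1e-10)
    }
  })
})

test_that("leaves partition the training matrix and children tile parents", {
  sim <- make_toy_net(9, 7, seed = 5)
  m <- nrlmf_fit(sim, nrlmf_config(k = 2, max_iters = 20))
  Yhat <- reconstruct(sim, m)
  for (s in 1:5) {
    tr <- grow_tree(Yhat, sim$X_d, sim$X_p, ensemble_config(seed = s))
    leaves <- extract_biclusters(tr)
    cover <- matrix(0L, nrow(Yhat), ncol(Yhat))
    for (b in leaves) cover[b$rows, b$cols] <- cover[b$rows, b$cols] + 1L
    expect_true(all(cover == 1L))  # disjoint and exhaustive
    sizes <- vapply(leaves, function(b) length(b$rows) * length(b$cols),
                    numeric(1))
    expect_equal(sum(sizes), length(Yhat))
    # every leaf value is its block mean
    for (b in leaves) {
      leaf_ids <- which(tr$axis == 0)
      expect_true(any(abs(tr$value[leaf_ids] -
                            mean(Yhat[b$rows, b$cols])) < 1e-12))
    }
  }
})

test_that("fully grown trees memorize their training matrix", {
  sim <- make_toy_net(8, 6, seed = 6)
  m <- nrlmf_fit(sim, nrlmf_config(k = 2, max_iters = 20))
  Yhat <- reconstruct(sim, m)
  # similarity features of distinct latent rows are injective in practice
  tr <- grow_tree(Yhat, sim$X_d, sim$X_p, ensemble_config(seed = 8))
  ens1 <- single_tree_ensemble(tr, ncol(sim$X_d), ncol(sim$X_p))
  pred <- predict_ensemble(ens1, sim$X_d, sim$X_p)
  expect_equal(unname(pred), unname(Yhat), tolerance = 1e-12)
})

test_that("ensembles are deterministic, sized, and averaged over trees", {
  sim <- make_toy_net(8, 6, seed = 7)
  m <- nrlmf_fit(sim, nrlmf_config(k = 2, max_iters = 20))
  Yhat <- reconstruct(sim, m)
  cfg <- ensemble_config(n_trees = 7, seed = 11)
  e1 <- fit_ensemble(Yhat, sim$X_d, sim$X_p, cfg)
  expect_length(e1$trees, 7)
  e2 <- fit_ensemble(Yhat, sim$X_d, sim$X_p, cfg)
  probe_d <- matrix(rnorm(2 * ncol(sim$X_d), sd = 0.5), 2)
  probe_p <- matrix(rnorm(2 * ncol(sim$X_p), sd = 0.5), 2)
  expect_identical(predict_ensemble(e1, probe_d, probe_p),
                   predict_ensemble(e2, probe_d, probe_p))
  # average of the individual trees
  per_tree <- sapply(e1$trees, function(t) {
    predict_ensemble(single_tree_ensemble(t, ncol(sim$X_d), ncol(sim$X_p)),
                     probe_d[1, , drop = FALSE],
                     probe_p[1, , drop = FALSE])[1, 1]
  })
  expect_equal(predict_ensemble(e1, probe_d[1, , drop = FALSE],
                                probe_p[1, , drop = FALSE])[1, 1],
               mean(per_tree), tolerance = 1e-12)
})

test_that("predictions stay within the training target range", {
  sim <- make_toy_net(10, 8, seed = 9)
  m <- nrlmf_fit(sim, nrlmf_config(k = 2, max_iters = 20))
  Yhat <- reconstruct(sim, m)
  ens <- fit_ensemble(Yhat, sim$X_d, sim$X_p,
                      ensemble_config(n_trees = 10, seed = 3))
  withr::with_seed(51, {
    probe_d <- matrix(rnorm(50), 5, ncol(sim$X_d))
    probe_p <- matrix(rnorm(40), 5, ncol(sim$X_p))
  })
  p <- predict_ensemble(ens, probe_d, probe_p)
  expect_true(all(p >= min(Yhat) - 1e-12 & p <= max(Yhat) + 1e-12))
})

test_that("manual traversal of a hand-built tree matches predict_pair", {
  # root: ROW split on drug feature 2 at 0.5; left child leaf 0.2;
  # right child: COLUMN split on protein feature 1 at 0 -> leaves 0.6 / 0.9
  tree <- structure(list(
    axis = c(1L, 0L, 2L, 0L, 0L),
    feature = c(2L, NA, 1L, NA, NA),
    threshold = c(0.5, NA, 0, NA, NA),
    left = c(2L, NA, 4L, NA, NA),
    right = c(3L, NA, 5L, NA, NA),
    value = c(NA, 0.2, NA, 0.6, 0.9),
    leaf_rows = list(NULL, 1L, NULL, 2L, 3L),
    leaf_cols = list(NULL, 1:2, NULL, 1:2, 1:2)), class = "bictr_tree")
  ens <- single_tree_ensemble(tree, 2, 1)
  expect_equal(predict_pair(ens, c(9, 0.4), 5), 0.2)
  expect_equal(predict_pair(ens, c(9, 0.6), -1), 0.6)
  expect_equal(predict_pair(ens, c(9, 0.6), 1), 0.9)
  expect_equal(predict_pair(ens, c(9, 0.6), 1),
               traverse_oracle(tree, c(9, 0.6), 1))
  expect_error(predict_pair(ens, c(1, 2, 3), 1), "length")
})

test_that("ensemble prediction variance shrinks as trees are added", {
  sim <- make_toy_net(10, 8, seed = 10)
  m <- nrlmf_fit(sim, nrlmf_config(k = 2, max_iters = 20))
  Yhat <- reconstruct(sim, m)
  # probe a NEW pair: training pairs are memorized identically by every
  # fully grown tree, so only off-training points vary across seeds
  withr::with_seed(52, {
    probe_d <- matrix(rnorm(ncol(sim$X_d), sd = 0.4), 1)
    probe_p <- matrix(rnorm(ncol(sim$X_p), sd = 0.4), 1)
  })
  spread <- sapply(c(1, 5, 25), function(nt) {
    preds <- sapply(1:12, function(s) {
      ens <- fit_ensemble(Yhat, sim$X_d, sim$X_p,
                          ensemble_config(n_trees = nt, seed = s))
      predict_ensemble(ens, probe_d, probe_p)[1, 1]
    })
    var(preds)
  })
  expect_gt(spread[1], spread[3])  # monotone trend across the range
})

test_that("JSON serialization round-trips ensembles bit-exactly", {
  sim <- make_toy_net(8, 6, seed = 12)
  m <- nrlmf_fit(sim, nrlmf_config(k = 2, max_iters = 15))
  Yhat <- reconstruct(sim, m)
  ens <- fit_ensemble(Yhat, sim$X_d, sim$X_p,
                      ensemble_config(n_trees = 3, seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, f)
  ens2 <- read_ensemble(f)
  probe_d <- matrix(rnorm(16), 2, ncol(sim$X_d))
  probe_p <- matrix(rnorm(12), 2, ncol(sim$X_p))
  expect_identical(predict_ensemble(ens, probe_d, probe_p),
                   predict_ensemble(ens2, probe_d, probe_p))
  for (t in seq_along(ens$trees)) {
    expect_identical(ens$trees[[t]]$threshold, ens2$trees[[t]]$threshold)
    expect_identical(ens$trees[[t]]$value, ens2$trees[[t]]$value)
  }
  expect_identical(extract_biclusters(ens$trees[[1]]),
                   extract_biclusters(ens2$trees[[1]]))
})
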