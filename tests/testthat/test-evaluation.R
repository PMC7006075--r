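test_that("fold plans partition nodes with near-equal sizes", {
  sim <- generate_synthetic(54, 26, rank = 3, density = 0.06, seed = 1)
  plan <- make_folds(sim$network, "td_lp", n_folds_drugs = 10, seed = 2)
  sizes <- lengths(lapply(plan$folds, `[[`, "test_drugs"))
  expect_true(all(sizes %in% c(5L, 6L)))
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test_drugs")), 1:54)

  plan_p <- make_folds(sim$network, "ld_tp", n_folds_proteins = 10, seed = 2)
  expect_setequal(unlist(lapply(plan_p$folds, `[[`, "test_proteins")), 1:26)

  plan_b <- make_folds(sim$network, "td_tp", n_folds_drugs = 5,
                       n_folds_proteins = 5, seed = 2)
  expect_length(plan_b$folds, 25)

  expect_error(make_folds(sim$network, "ld_tp", n_folds_proteins = 30),
               "exceeds")
})

test_that("fold plans export and import exactly", {
  sim <- generate_synthetic(20, 15, rank = 2, density = 0.1, seed = 3)
  plan <- make_folds(sim$network, "td_tp", 4, 3, seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, f)
  plan2 <- read_fold_plan(f)
  expect_identical(plan2$setting, plan$setting)
  expect_identical(plan2$folds, plan$folds)
})

test_that("auroc matches its threshold-enumeration oracle, ties included", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(61, {
    for (rep in 1:30) {
      n <- 50
      scores <- if (rep %% 2 == 0) runif(n) else
        sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      labels <- rbinom(n, 1, 0.3)
      if (sum(labels) == 0 || sum(labels) == n) next
      expect_equal(auroc(scores, labels), auroc_oracle(scores, labels),
                   tolerance = 1e-10)
    }
  })
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "negatives")
  expect_error(auroc(c(0.1, 0.2), c(0, 0)), "positives")
})

test_that("aupr matches its rank-accumulation oracle, ties included", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aupr(seq(1, 0.1, length.out = 10), c(rep(0, 9), 1)), 0.1)
  withr::with_seed(62, {
    for (rep in 1:30) {
      n <- 50
      scores <- if (rep %% 2 == 0) runif(n) else
        sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      labels <- rbinom(n, 1, 0.3)
      if (sum(labels) == 0) next
      expect_equal(aupr(scores, labels), aupr_oracle(scores, labels),
                   tolerance = 1e-10)
    }
  })
  expect_error(aupr(c(0.1, 0.2), c(0, 0)), "positives")
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(63, {
    for (rep in 1:10) {
      scores <- round(runif(40), 2)
      labels <- rbinom(40, 1, 0.4)
      if (length(unique(labels)) < 2) next
      ref <- suppressMessages(
        as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                       direction = "<"))))
      expect_equal(auroc(scores, labels), ref, tolerance = 1e-10)
    }
  })
})

test_that("micro pooling is associative and differs from macro averaging", {
  s1 <- c(0.9, 0.1, 0.8, 0.3)
  l1 <- c(1, 0, 0, 0)
  s2 <- c(0.7, 0.6, 0.2)
  l2 <- c(1, 1, 0)
  pooled <- auroc(c(s1, s2), c(l1, l2))
  expect_equal(pooled, auroc_oracle(c(s1, s2), c(l1, l2)), tolerance = 1e-10)
  macro <- mean(c(auroc(s1, l1), auroc(s2, l2)))
  expect_false(isTRUE(all.equal(pooled, macro)))
})

test_that("no fold leaks a test instance's interaction profile into training", {
  sim <- generate_synthetic(24, 18, rank = 3, density = 0.1, seed = 4)
  n_d <- 24
  n_p <- 18
  for (s in 1:5) {
    for (setting in c("td_lp", "ld_tp", "td_tp")) {
      plan <- make_folds(sim$network, setting, n_folds_drugs = 4,
                         n_folds_proteins = 3, seed = s)
      seen_d <- integer(0)
      seen_p <- integer(0)
      for (fold in plan$folds) {
        td <- fold$test_drugs
        tp <- fold$test_proteins
        train_d <- setdiff(seq_len(n_d), td)
        train_p <- setdiff(seq_len(n_p), tp)
        expect_length(intersect(td, train_d), 0)
        expect_length(intersect(tp, train_p), 0)
        seen_d <- c(seen_d, td)
        seen_p <- c(seen_p, tp)
      }
      if (setting == "td_lp") expect_setequal(seen_d, 1:n_d)
      if (setting == "ld_tp") expect_setequal(seen_p, 1:n_p)
      if (setting == "td_tp") {
        expect_length(plan$folds, 12)
        # every (drug, protein) pair is tested exactly once
        hits <- matrix(0L, n_d, n_p)
        for (fold in plan$folds) {
          hits[fold$test_drugs, fold$test_proteins] <-
            hits[fold$test_drugs, fold$test_proteins] + 1L
        }
        expect_true(all(hits == 1L))
      }
    }
  }
})

test_that("experiments pool pairs across folds (micro) and keep per-fold rows", {
  sim <- generate_synthetic(24, 16, rank = 3, density = 0.12, seed = 5)
  res <- run_experiment(sim$network, "td_lp", "bictr", n_folds_drugs = 4,
                        nrlmf_cfg = nrlmf_config(k = 3, max_iters = 25),
                        ens_cfg = ensemble_config(n_trees = 5), seed = 6)
  expect_s3_class(res, "bictr_eval")
  expect_equal(nrow(res$per_fold), 4)
  kept <- res$per_fold$kept
  expect_equal(sum(res$per_fold$n_pairs[kept]), length(res$scores))
  # pooled metric equals the metric of the concatenated arrays
  expect_equal(res$auroc, auroc(res$scores, res$labels))
  expect_equal(res$aupr, aupr(res$scores, res$labels))
  # and generally differs from the per-fold mean (micro vs macro)
  expect_false(isTRUE(all.equal(res$auroc,
                                mean(res$per_fold$auroc[kept]))))
})

test_that("a perfect oracle method attains AUROC 1 under the protocol", {
  sim <- generate_synthetic(18, 14, rank = 2, density = 0.15, seed = 7)
  plan <- make_folds(sim$network, "td_lp", n_folds_drugs = 3, seed = 8)
  scores <- c()
  labels <- c()
  for (fold in plan$folds) {
    td <- fold$test_drugs
    # inject the ground truth as the prediction
    scores <- c(scores, as.vector(sim$network$Y[td, ] + 0))
    labels <- c(labels, as.vector(sim$network$Y[td, ]))
  }
  expect_equal(auroc(scores, labels), 1.0)
})

test_that("experiment runs are reproducible and setting-consistent", {
  sim <- generate_synthetic(20, 14, rank = 2, density = 0.15, seed = 9)
  a <- run_experiment(sim$network, "td_tp", "ebict", n_folds_drugs = 3,
                      n_folds_proteins = 3,
                      ens_cfg = ensemble_config(n_trees = 4), seed = 11)
  b <- run_experiment(sim$network, "td_tp", "ebict", n_folds_drugs = 3,
                      n_folds_proteins = 3,
                      ens_cfg = ensemble_config(n_trees = 4), seed = 11)
  expect_identical(a$auroc, b$auroc)
  expect_identical(a$scores, b$scores)
  expect_equal(nrow(a$per_fold), 9)
})

test_that("nested CV returns the planted optimum and the full grids enumerate", {
  expect_equal(nrow(nrlmf_grid()), 4^5 * 3 * 2)
  g <- grid_subset(nrlmf_grid(), 20, seed = 1)
  expect_equal(nrow(g), 20)
  expect_identical(g, grid_subset(nrlmf_grid(), 20, seed = 1))

  sim <- generate_synthetic(16, 12, rank = 2, density = 0.15, seed = 10)
  grid <- data.frame(k = c(2, 3, 4), learning_rate = 0.25)
  planted <- function(net, params, fold_plan) rep(-abs(params$k - 3), 2)
  fit <- nested_cv_tune(sim$network, grid, setting = "td_lp",
                        inner_folds = 3, seed = 12, score_fun = planted)
  expect_equal(fit$best$k, 3)
  expect_equal(fit$best_config$k, 3L)

  # singleton grid returned unchanged without inner fitting
  single <- nested_cv_tune(sim$network, grid[2, , drop = FALSE],
                           setting = "td_lp", inner_folds = 3, seed = 12,
                           score_fun = function(...) stop("should not fit"))
  expect_equal(single$best$k, 3)

  # failing grid points are skipped and recorded
  flaky <- function(net, params, fold_plan) {
    if (params$k == 2) stop("diverged") else rep(params$k, 2)
  }
  fit2 <- nested_cv_tune(sim$network, grid, setting = "td_lp",
                         inner_folds = 3, seed = 12, score_fun = flaky)
  expect_equal(fit2$best$k, 4)
  expect_length(fit2$failures, 1)
})

test_that("config files read from YAML and key=value dialects", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nrlmf:", "  k: 10", "  c: 5", "ensemble:", "  n_trees: 50"), f)
  cfg <- read_bictr_config(f)
  expect_equal(cfg$nrlmf$k, 10L)
  expect_equal(cfg$ensemble$n_trees, 50L)
  expect_equal(cfg$nrlmf$lambda_d, 0.5)  # default retained

  g <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("nrlmf.k = 7", "ensemble.exhaustive = true  # comment"), g)
  cfg2 <- read_bictr_config(g)
  expect_equal(cfg2$nrlmf$k, 7L)
  expect_true(cfg2$ensemble$exhaustive)

  h <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nrlmf:", "  bogus: 1"), h)
  expect_error(read_bictr_config(h), "unknown nrlmf")
})
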