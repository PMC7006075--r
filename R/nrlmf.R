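#' NRLMF hyperparameter configuration
#'
#' Neighborhood-regularized logistic matrix factorization models the
#' probability that drug i interacts with protein j as
#' `sigma(u_i . v_j)`, with zero-mean Gaussian priors on the latent vectors
#' (L2 terms `lambda_d`, `lambda_p`) and graph-Laplacian smoothness terms
#' (`alpha`, `beta`) over K-nearest-neighbor similarity graphs of drugs and
#' proteins. Observed interacting pairs are up-weighted by `c` (each 1 in
#' the matrix counts as `c` positives), mitigating class imbalance.
#'
#' Defaults sit at the centers of the usual tuning grids for this model
#' family: `lambda_d`, `lambda_p`, `alpha`, `beta` and the learning rate in
#' `{2^-2, ..., 2^1}`, neighbors in `{3, 5, 10}`, latent dimension in
#' `{50, 100}`, and `c = 5`.
#'
#' @param k latent dimension.
#' @param c importance weight of observed interactions, `c >= 1`.
#' @param lambda_d,lambda_p L2 regularization weights (drugs/proteins).
#' @param alpha,beta graph regularization weights (drugs/proteins).
#' @param n_neighbors neighbors K for the similarity graphs.
#' @param learning_rate AdaGrad base learning rate.
#' @param max_iters gradient iterations.
#' @param seed seed for the latent initialization.
#' @return An object of class `nrlmf_config`.
#' @export
nrlmf_config <- function(k = 50, c = 5, lambda_d = 0.5, lambda_p = 0.5,
                         alpha = 0.5, beta = 0.5, n_neighbors = 5,
                         learning_rate = 0.25, max_iters = 100, seed = 1) {
  stopifnot(k >= 1, n_neighbors >= 1, learning_rate > 0, max_iters >= 1)
  if (c < 1) stop("c must be >= 1")
  if (min(lambda_d, lambda_p, alpha, beta) < 0) {
    stop("regularization weights must be nonnegative")
  }
  structure(
    list(k = as.integer(k), c = c, lambda_d = lambda_d, lambda_p = lambda_p,
         alpha = alpha, beta = beta, n_neighbors = as.integer(n_neighbors),
         learning_rate = learning_rate, max_iters = as.integer(max_iters),
         seed = as.integer(seed)),
    class = "nrlmf_config")
}

#' Build a K-nearest-neighbor graph and its Laplacian from a similarity matrix
#'
#' For each instance the K most similar other instances (self excluded) are
#' its neighbors. The adjacency keeps the raw similarity value on an edge
#' if either endpoint selects the other (mutual-or-one-sided KNN) and is
#' symmetrized as `(A + t(A))/2`. The Laplacian is the unnormalized
#' combinatorial form `L = diag(rowSums(A)) - A`, whose quadratic form
#' `Tr(U' L U)` penalizes latent differences between similar instances.
#'
#' @param S square similarity matrix.
#' @param K number of nearest neighbors, `K < nrow(S)`.
#' @return An object of class `neighbor_graph`: list with adjacency `A` and
#'   Laplacian `L`.
#' @export
build_neighbor_graph <- function(S, K) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  n <- nrow(S)
  if (K >= n) stop(sprintf("K = %d must be smaller than n = %d", K, n))
  stopifnot(K >= 1)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(s, decreasing = TRUE)[seq_len(K)]
    # negative similarities (possible with cosine features) carry no
    # neighborhood information; clamp so A stays nonnegative and L PSD
    A[i, nb] <- pmax(S[i, nb], 0)
  }
  A <- (A + t(A)) / 2
  diag(A) <- 0
  L <- diag(rowSums(A), n) - A
  structure(list(A = A, L = L), class = "neighbor_graph")
}

# Stable softplus: ln(1 + exp(x)) without overflow.
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Interaction probability from latent vectors
#'
#' Computes `exp(u.v) / (1 + exp(u.v))`, the logistic link of the latent
#' inner product, in overflow-free form.
#'
#' @param u,v numeric latent vectors of equal length.
#' @return A probability in (0, 1\].
#' @export
logistic_score <- function(u, v) {
  if (length(u) != length(v)) stop("latent vectors differ in length")
  plogis(sum(u * v))
}

#' NRLMF objective function
#'
#' Evaluates the penalized negative log-likelihood
#' `sum_ij (1 + c*Y - Y) * ln(1 + exp(u_i.v_j)) - c*Y_ij * u_i.v_j
#'  + lambda_d ||U||_F^2 + lambda_p ||V||_F^2
#'  + alpha Tr(U' L_d U) + beta Tr(V' L_p V)`.
#' With `c = 1` and all regularizers 0 this is exactly the negative
#' Bernoulli log-likelihood of `Y` under the logistic link.
#'
#' @param U,V latent factor matrices (`|D| x k`, `|P| x k`).
#' @param Y binary interaction matrix.
#' @param graph_d,graph_p [build_neighbor_graph()] objects for drugs and
#'   proteins, or `NULL` when `alpha`/`beta` are 0.
#' @param config an [nrlmf_config()].
#' @return Scalar objective value.
#' @export
nrlmf_objective <- function(U, V, Y, graph_d = NULL, graph_p = NULL, config) {
  check_latent_shapes(U, V, Y, config)
  Z <- tcrossprod(U, V)
  W <- 1 + config$c * Y - Y
  obj <- sum(W * softplus(Z)) - config$c * sum(Y * Z) +
    config$lambda_d * sum(U^2) + config$lambda_p * sum(V^2)
  if (config$alpha > 0) {
    obj <- obj + config$alpha * sum(U * (graph_d$L %*% U))
  }
  if (config$beta > 0) {
    obj <- obj + config$beta * sum(V * (graph_p$L %*% V))
  }
  obj
}

#' Analytic gradient of the NRLMF objective
#'
#' `dU = (P * W - c*Y) V + 2 lambda_d U + 2 alpha L_d U` where `P` is the
#' logistic score matrix and `W = 1 + c*Y - Y` elementwise; symmetrically
#' for `dV`.
#'
#' @inheritParams nrlmf_objective
#' @return List with matrices `dU` and `dV`.
#' @export
nrlmf_gradient <- function(U, V, Y, graph_d = NULL, graph_p = NULL, config) {
  check_latent_shapes(U, V, Y, config)
  Z <- tcrossprod(U, V)
  P <- plogis(Z)
  W <- 1 + config$c * Y - Y
  G <- P * W - config$c * Y
  dU <- G %*% V + 2 * config$lambda_d * U
  dV <- crossprod(G, U) + 2 * config$lambda_p * V
  if (config$alpha > 0) dU <- dU + 2 * config$alpha * (graph_d$L %*% U)
  if (config$beta > 0) dV <- dV + 2 * config$beta * (graph_p$L %*% V)
  list(dU = dU, dV = dV)
}

check_latent_shapes <- function(U, V, Y, config) {
  if (ncol(U) != ncol(V)) stop("U and V must share the latent dimension")
  if (nrow(U) != nrow(Y) || nrow(V) != ncol(Y)) {
    stop(sprintf(
      "shape mismatch: U is %d x %d, V is %d x %d, Y is %d x %d",
      nrow(U), ncol(U), nrow(V), ncol(V), nrow(Y), ncol(Y)))
  }
  invisible(TRUE)
}

# Similarity used for the neighbor graphs: square feature matrices are
# taken as similarities directly (the benchmark convention); rectangular
# feature matrices fall back to cosine similarity of their rows, keeping
# the method applicable to arbitrary feature spaces.
feature_similarity <- function(X) {
  if (nrow(X) == ncol(X)) return(X)
  cosine_similarity(X)
}

#' Fit NRLMF latent factors
#'
#' Minimizes the objective of [nrlmf_objective()] by AdaGrad gradient
#' descent from a seeded `N(0, 1/k)` initialization, recording the
#' objective value at each iteration. Neighbor graphs are built from the
#' network's feature matrices (square matrices are treated as
#' similarities; rectangular ones are converted via cosine similarity of
#' rows); the neighbor count is capped at `n - 1` for small networks.
#'
#' @param net a [dti_network()].
#' @param config an [nrlmf_config()].
#' @return An object of class `nrlmf_model`: list with `U`, `V`, `config`,
#'   `objective_trace`, and the two neighbor graphs.
#' @export
nrlmf_fit <- function(net, config = nrlmf_config()) {
  stopifnot(inherits(net, "dti_network"), inherits(config, "nrlmf_config"))
  Y <- net$Y
  n_d <- nrow(Y)
  n_p <- ncol(Y)
  k <- config$k
  graph_d <- graph_p <- NULL
  if (config$alpha > 0) {
    graph_d <- build_neighbor_graph(feature_similarity(net$X_d),
                                    min(config$n_neighbors, n_d - 1L))
  }
  if (config$beta > 0) {
    graph_p <- build_neighbor_graph(feature_similarity(net$X_p),
                                    min(config$n_neighbors, n_p - 1L))
  }
  with_seed(derive_seed(config$seed, 10L), {
    U <- matrix(rnorm(n_d * k, sd = 1 / sqrt(k)), n_d, k)
    V <- matrix(rnorm(n_p * k, sd = 1 / sqrt(k)), n_p, k)
  })
  GU <- matrix(0, n_d, k)
  GV <- matrix(0, n_p, k)
  eps <- 1e-8
  trace <- numeric(config$max_iters)
  for (it in seq_len(config$max_iters)) {
    g <- nrlmf_gradient(U, V, Y, graph_d, graph_p, config)
    GU <- GU + g$dU^2
    GV <- GV + g$dV^2
    U <- U - config$learning_rate * g$dU / sqrt(GU + eps)
    V <- V - config$learning_rate * g$dV / sqrt(GV + eps)
    trace[it] <- nrlmf_objective(U, V, Y, graph_d, graph_p, config)
    if (!is.finite(trace[it])) {
      stop("NRLMF objective became non-finite; try a smaller learning_rate")
    }
  }
  structure(
    list(U = U, V = V, config = config, objective_trace = trace,
         graph_d = graph_d, graph_p = graph_p),
    class = "nrlmf_model")
}

#' @export
print.nrlmf_model <- function(x, ...) {
  cat(sprintf(
    "<nrlmf_model> %d x %d latent factors (k = %d), %d iterations\n",
    nrow(x$U), nrow(x$V), ncol(x$U), length(x$objective_trace)))
  cat(sprintf("  objective: %.4f -> %.4f\n",
              x$objective_trace[1], tail_value(x$objective_trace)))
  invisible(x)
}

tail_value <- function(x) x[length(x)]

#' Plot the NRLMF objective trace
#'
#' @param x an `nrlmf_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nrlmf_model <- function(x, ...) {
  graphics::plot(seq_along(x$objective_trace), x$objective_trace,
                 type = "l", xlab = "iteration", ylab = "objective", ...)
  invisible(x)
}

#' Write an objective trace as two-column delimited text
#'
#' @param model an `nrlmf_model`.
#' @param path output file.
#' @export
write_objective_trace <- function(model, path) {
  stopifnot(inherits(model, "nrlmf_model"))
  writeLines(c("iteration\tobjective",
               sprintf("%d\t%.17g", seq_along(model$objective_trace),
                       model$objective_trace)),
             path)
  invisible(path)
}

#' Reconstruct the interaction matrix from fitted latent factors
#'
#' Verified interactions are preserved exactly: wherever `Y[i,j] == 1` the
#' reconstructed entry is 1. Every other entry is replaced by the logistic
#' interaction probability, clipped into the open interval (0, 1) so that
#' exact ones identify the observed interactions uniquely.
#'
#' @param net the training [dti_network()].
#' @param model an `nrlmf_model` fitted on `net`.
#' @return Numeric matrix of the same shape as `net$Y` with entries in
#'   (0, 1\].
#' @export
reconstruct <- function(net, model) {
  stopifnot(inherits(net, "dti_network"), inherits(model, "nrlmf_model"))
  if (nrow(model$U) != nrow(net$Y) || nrow(model$V) != ncol(net$Y)) {
    stop("latent model dimensions do not match the network")
  }
  P <- plogis(tcrossprod(model$U, model$V))
  eps <- 1e-12
  P <- pmin(pmax(P, eps), 1 - eps)
  P[net$Y == 1] <- 1
  dimnames(P) <- dimnames(net$Y)
  P
}
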