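#' Generate a synthetic DTI network with known ground truth
#'
#' Emulates the sparse bipartite interaction networks of the chemogenomics
#' benchmarks (densities of roughly 1-7%) from a low-rank logistic latent
#' model. Latent factors `true_U` (drugs) and `true_V` (proteins) are drawn
#' i.i.d. normal with sd `1/sqrt(rank)`; the interaction probability of a
#' pair is the logistic function of the latent inner product, and `Y` is
#' obtained by thresholding the probability matrix at the quantile that
#' yields the requested density. Feature matrices are the cosine-similarity
#' matrices of the latent rows plus optional Gaussian noise, mirroring the
#' similarity-based drug/protein descriptors of the benchmark data.
#'
#' Setting `hidden_fraction > 0` flips that fraction of the true
#' interactions to 0, emulating the positive-unlabeled character of real
#' DTI networks, where an observed 0 may be an unreported interaction. The
#' returned `hidden_mask` marks the flipped cells, and `Y_true` restores
#' them, so recovery of hidden positives can be measured against ground
#' truth.
#'
#' @param n_drugs,n_proteins network dimensions.
#' @param rank true latent dimension; must not exceed
#'   `min(n_drugs, n_proteins)`.
#' @param density target fraction of ones in the uncorrupted matrix,
#'   strictly in (0, 1).
#' @param feature_noise sd of the Gaussian noise added to the similarity
#'   features (0 = noise-free).
#' @param hidden_fraction fraction of true interactions flipped to 0,
#'   in \[0, 1).
#' @param seed integer seed; all randomness derives from it.
#' @return A list with elements `network` (a [dti_network()] whose `Y` has
#'   the hidden positives removed), `true_U`, `true_V`, `hidden_mask`
#'   (binary matrix marking flipped cells), `Y_true` (uncorrupted binary
#'   matrix) and `threshold` (the probability cutoff used).
#' @examples
#' sim <- generate_synthetic(20, 15, rank = 3, density = 0.1, seed = 1)
#' network_stats(sim$network)
#' @export
generate_synthetic <- function(n_drugs, n_proteins, rank, density,
                               feature_noise = 0, hidden_fraction = 0,
                               seed = 1) {
  stopifnot(n_drugs >= 2, n_proteins >= 2, rank >= 1)
  if (rank > min(n_drugs, n_proteins)) {
    stop("rank must not exceed min(n_drugs, n_proteins)")
  }
  if (!(density > 0 && density < 1)) stop("density must lie strictly in (0, 1)")
  if (!(hidden_fraction >= 0 && hidden_fraction < 1)) {
    stop("hidden_fraction must lie in [0, 1)")
  }
  if (feature_noise < 0) stop("feature_noise must be nonnegative")

  with_seed(derive_seed(seed, 1L), {
    U <- matrix(rnorm(n_drugs * rank, sd = 1 / sqrt(rank)), n_drugs, rank)
    V <- matrix(rnorm(n_proteins * rank, sd = 1 / sqrt(rank)), n_proteins, rank)
  })
  P <- plogis(tcrossprod(U, V))
  thr <- quantile(P, probs = 1 - density, names = FALSE, type = 7)
  Y_true <- (P > thr) * 1
  n_ones <- sum(Y_true)
  n_cells <- n_drugs * n_proteins
  if (abs(n_ones / n_cells - density) > 0.2 * density) {
    stop(sprintf(
      "requested density %.3g unattainable (realized %.3g); latent model too degenerate",
      density, n_ones / n_cells))
  }

  hidden_mask <- matrix(0, n_drugs, n_proteins)
  Y <- Y_true
  n_hide <- round(hidden_fraction * n_ones)
  if (n_hide > 0) {
    ones <- which(Y_true == 1)
    hide <- with_seed(derive_seed(seed, 2L), sample(ones, n_hide))
    hidden_mask[hide] <- 1
    Y[hide] <- 0
  }

  X_d <- cosine_similarity(U)
  X_p <- cosine_similarity(V)
  if (feature_noise > 0) {
    with_seed(derive_seed(seed, 3L), {
      X_d <- X_d + matrix(rnorm(length(X_d), sd = feature_noise), nrow(X_d))
      X_p <- X_p + matrix(rnorm(length(X_p), sd = feature_noise), nrow(X_p))
    })
  }

  net <- dti_network(Y, X_d, X_p)
  dimnames(hidden_mask) <- dimnames(net$Y)
  dimnames(Y_true) <- dimnames(net$Y)
  list(network = net, true_U = U, true_V = V, hidden_mask = hidden_mask,
       Y_true = Y_true, threshold = thr)
}

# Row-wise cosine similarity; zero rows yield zero similarity.
cosine_similarity <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  Xn <- X / nrm
  S <- tcrossprod(Xn)
  pmin(pmax(S, -1), 1)
}
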