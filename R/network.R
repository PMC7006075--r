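#' Construct a bipartite drug-target interaction network
#'
#' Bundles a binary interaction matrix `Y` (drugs as rows, proteins as
#' columns) with a drug feature matrix `X_d` and a protein feature matrix
#' `X_p`. In the standard chemogenomics benchmarks the feature matrices are
#' square similarity matrices (chemical-structure similarity between drugs,
#' normalized Smith-Waterman similarity between protein sequences), but any
#' rectangular numeric feature matrix is accepted.
#'
#' @param Y numeric matrix with entries in \{0, 1\}; rows are drugs,
#'   columns are proteins.
#' @param X_d numeric drug feature matrix with `nrow(Y)` rows.
#' @param X_p numeric protein feature matrix with `ncol(Y)` rows.
#' @param drug_ids,protein_ids optional unique identifier vectors; defaults
#'   are taken from the dimnames of `Y` or generated as `d1, d2, ...` /
#'   `p1, p2, ...`.
#' @return An object of class `dti_network`: a list with elements `Y`,
#'   `X_d`, `X_p`, `drug_ids`, `protein_ids`.
#' @examples
#' Y <- matrix(c(0, 1, 1, 0), 2, 2)
#' net <- dti_network(Y, diag(2), diag(2))
#' network_stats(net)
#' @export
dti_network <- function(Y, X_d, X_p, drug_ids = NULL, protein_ids = NULL) {
  Y <- as.matrix(Y)
  X_d <- as.matrix(X_d)
  X_p <- as.matrix(X_p)
  if (anyNA(Y)) stop("interaction matrix contains missing values")
  bad <- which(!(Y == 0 | Y == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "interaction matrix must be binary; found value %g at row %d, column %d",
      Y[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  }
  if (nrow(X_d) != nrow(Y)) {
    stop(sprintf(
      "drug feature matrix has %d rows but interaction matrix has %d drugs",
      nrow(X_d), nrow(Y)))
  }
  if (nrow(X_p) != ncol(Y)) {
    stop(sprintf(
      "protein feature matrix has %d rows but interaction matrix has %d proteins",
      nrow(X_p), ncol(Y)))
  }
  if (is.null(drug_ids)) {
    drug_ids <- rownames(Y)
    if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(nrow(Y)))
  }
  if (is.null(protein_ids)) {
    protein_ids <- colnames(Y)
    if (is.null(protein_ids)) protein_ids <- paste0("p", seq_len(ncol(Y)))
  }
  drug_ids <- as.character(drug_ids)
  protein_ids <- as.character(protein_ids)
  if (length(drug_ids) != nrow(Y) || anyDuplicated(drug_ids)) {
    stop("drug_ids must be unique and match nrow(Y)")
  }
  if (length(protein_ids) != ncol(Y) || anyDuplicated(protein_ids)) {
    stop("protein_ids must be unique and match ncol(Y)")
  }
  storage.mode(Y) <- "double"
  dimnames(Y) <- list(drug_ids, protein_ids)
  rownames(X_d) <- drug_ids
  rownames(X_p) <- protein_ids
  structure(
    list(Y = Y, X_d = X_d, X_p = X_p,
         drug_ids = drug_ids, protein_ids = protein_ids),
    class = "dti_network")
}

#' @export
print.dti_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(
    "<dti_network> %d drugs x %d proteins, %d interactions (density %.3f)\n",
    s$n_drugs, s$n_proteins, s$n_interactions, s$density))
  cat(sprintf("  drug features: %d x %d; protein features: %d x %d\n",
              nrow(x$X_d), ncol(x$X_d), nrow(x$X_p), ncol(x$X_p)))
  invisible(x)
}

#' Summarize a DTI network
#'
#' @param net a [dti_network()].
#' @return One-row data frame with `n_drugs`, `n_proteins`,
#'   `n_interactions` and `density` (interactions per drug-protein pair).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "dti_network"))
  n_d <- nrow(net$Y)
  n_p <- ncol(net$Y)
  m <- sum(net$Y)
  data.frame(n_drugs = n_d, n_proteins = n_p, n_interactions = as.integer(m),
             density = m / (n_d * n_p))
}

# Read a whitespace/tab-delimited numeric matrix, tolerating an optional
# header row and an optional leading label column (the benchmark sites ship
# both dialects). Detection: a first token that does not parse as a number
# signals a header / label column.
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path)
  toks <- strsplit(trimws(lines), "[ \t,]+")
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  header <- NULL
  # header row iff the first row's LAST token is non-numeric (a label
  # column alone leaves the trailing tokens numeric)
  first_row <- toks[[1]]
  if (!is_num(first_row[[length(first_row)]])) {
    header <- toks[[1]]
    toks <- toks[-1]
    if (length(toks) == 0) stop("matrix file has a header but no data: ", path)
  }
  labels <- NULL
  first_col <- vapply(toks, `[[`, character(1), 1L)
  if (!all(is_num(first_col))) {
    labels <- first_col
    toks <- lapply(toks, `[`, -1L)
  }
  ncols <- unique(lengths(toks))
  if (length(ncols) != 1) {
    stop(sprintf("ragged rows in %s: widths %s", path,
                 paste(ncols, collapse = ", ")))
  }
  # a header of ncol+1 tokens labels the label column too; trim from front
  if (!is.null(header) && length(header) == ncols + 1L) header <- header[-1L]
  M <- matrix(as.numeric(unlist(toks)), nrow = length(toks), ncol = ncols,
              byrow = TRUE)
  if (anyNA(M)) stop("non-numeric entries in matrix file: ", path)
  if (!is.null(labels)) rownames(M) <- labels
  if (!is.null(header) && length(header) == ncols) colnames(M) <- header
  M
}

#' Load a DTI network from delimited text files
#'
#' Each file is a whitespace-, tab- or comma-delimited numeric matrix,
#' optionally carrying a header row of identifiers and/or a leading label
#' column (auto-detected). The interaction matrix must be oriented drugs as
#' rows, proteins as columns, and strictly binary. Feature matrices are
#' used as-is; no symmetrization or other post-processing is applied.
#'
#' @param interaction_path path to the binary interaction matrix.
#' @param drug_feature_path path to the drug feature matrix (one row per
#'   drug).
#' @param protein_feature_path path to the protein feature matrix (one row
#'   per protein).
#' @return A [dti_network()].
#' @export
load_network <- function(interaction_path, drug_feature_path,
                         protein_feature_path) {
  Y <- read_matrix_file(interaction_path)
  X_d <- read_matrix_file(drug_feature_path)
  X_p <- read_matrix_file(protein_feature_path)
  if (nrow(X_d) != nrow(Y)) {
    stop(sprintf(
      "dimension mismatch: interaction matrix is %d x %d but drug feature matrix is %d x %d",
      nrow(Y), ncol(Y), nrow(X_d), ncol(X_d)))
  }
  if (nrow(X_p) != ncol(Y)) {
    stop(sprintf(
      "dimension mismatch: interaction matrix is %d x %d but protein feature matrix is %d x %d",
      nrow(Y), ncol(Y), nrow(X_p), ncol(X_p)))
  }
  dti_network(Y, X_d, X_p)
}

#' Write a DTI network as delimited text files
#'
#' Writes `interactions.txt`, `drug_features.txt` and
#' `protein_features.txt` under `dir` in the same dialect [load_network()]
#' reads (tab-delimited, header row of identifiers, leading label column).
#' Numeric values are written with 17 significant digits so a load/write
#' cycle round-trips bit-exactly.
#'
#' @param net a [dti_network()].
#' @param dir output directory, created if missing.
#' @return Invisibly, the three file paths.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "dti_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("interactions.txt", "drug_features.txt",
                            "protein_features.txt"))
  write_matrix_file(net$Y, paths[1])
  write_matrix_file(net$X_d, paths[2])
  write_matrix_file(net$X_p, paths[3])
  invisible(paths)
}

write_matrix_file <- function(M, path) {
  rn <- rownames(M)
  cn <- colnames(M)
  body <- apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  if (!is.null(rn)) body <- paste(rn, body, sep = "\t")
  lines <- body
  if (!is.null(cn)) lines <- c(paste(cn, collapse = "\t"), body)
  writeLines(lines, path)
  invisible(path)
}
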