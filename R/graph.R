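#' Sample-by-sample Pearson correlation matrix
#'
#' Correlates the feature vectors of every pair of samples (rows). Rows with
#' zero variance have no defined correlation with anything; their
#' off-diagonal entries are set to 0 with a warning so that they simply end
#' up isolated in the thresholded graph.
#'
#' @param X numeric matrix, samples in rows, at least two columns.
#' @return symmetric matrix in \[-1, 1\] with unit diagonal.
#' @export
pearson_matrix <- function(X) {
  X <- as_numeric_matrix(X)
  if (nrow(X) < 2L) stop("need at least two samples")
  if (ncol(X) < 2L) stop("correlation between samples is ill-defined with a single feature")
  Xc <- X - rowMeans(X)
  norms <- sqrt(rowSums(Xc^2))
  if (any(norms == 0)) {
    warning(sum(norms == 0), " zero-variance sample row(s); correlations set to 0")
    norms[norms == 0] <- Inf # those rows correlate with nothing
  }
  R <- tcrossprod(Xc / norms)
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

#' Threshold a correlation matrix into a binary adjacency
#'
#' An edge joins samples i and j (i != j) when their correlation meets the
#' threshold. The default rule is signed (`r >= threshold`), matching
#' positive co-expression thresholds such as 0.3 (GE) and 0.6 (CNA);
#' `absolute = TRUE` switches to `|r| >= threshold`.
#'
#' @param R symmetric correlation matrix.
#' @param threshold correlation cutoff in \[-1, 1\].
#' @param absolute use the absolute-value rule.
#' @return binary symmetric adjacency matrix with zero diagonal.
#' @export
build_adjacency <- function(R, threshold, absolute = FALSE) {
  R <- as_numeric_matrix(R, "R")
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("R must be symmetric")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < -1 || threshold > 1) {
    stop("threshold must be a single value in [-1, 1]")
  }
  M <- if (absolute) abs(R) else R
  A <- (M >= threshold) * 1
  diag(A) <- 0
  A
}

#' Symmetric normalization of an adjacency matrix
#'
#' Returns the propagation matrix `D^(-1/2) A D^(-1/2)` used by graph
#' convolution. With `add_self_loops = TRUE` (default) the augmented
#' adjacency `A + I` and its degrees are used, so every node retains its own
#' features and no degree is zero; without self-loops, isolated nodes
#' produce zero rows with a warning.
#'
#' @param A binary (or nonnegative) symmetric adjacency.
#' @param add_self_loops augment with the identity before normalizing.
#' @return sparse symmetric propagation matrix (spectral radius <= 1).
#' @export
normalize_adjacency <- function(A, add_self_loops = TRUE) {
  A <- as_numeric_matrix(A, "A")
  if (!isSymmetric(unname(A), tol = 0)) stop("adjacency must be symmetric")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  At <- if (add_self_loops) A + diag(nrow(A)) else A
  d <- rowSums(At)
  if (any(d == 0)) {
    warning(sum(d == 0), " isolated node(s) produce zero rows in the propagation matrix")
  }
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  An <- At * outer(dinv, dinv)
  dimnames(An) <- dimnames(A)
  Matrix::Matrix(An, sparse = TRUE)
}

#' Build a patient-similarity graph from a feature matrix
#'
#' Convenience constructor tying together [pearson_matrix()],
#' [build_adjacency()] and [normalize_adjacency()]: nodes are samples, edges
#' join pairs whose Pearson correlation meets `threshold`, and the
#' symmetric-normalized propagation matrix is precomputed for graph
#' convolution over the node features `X`.
#'
#' @param X numeric node-feature matrix (samples in rows).
#' @param threshold correlation cutoff.
#' @param absolute threshold on `|r|` instead of signed `r`.
#' @param add_self_loops see [normalize_adjacency()].
#' @return an object of class `sample_graph` with fields `node_ids`, `A`,
#'   `degree`, `A_norm`, `X`, `threshold`, `R`.
#' @export
sample_graph <- function(X, threshold, absolute = FALSE, add_self_loops = TRUE) {
  X <- as_numeric_matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%04d", seq_len(nrow(X)))
  R <- pearson_matrix(X)
  A <- build_adjacency(R, threshold, absolute)
  structure(
    list(
      node_ids = rownames(X),
      A = A,
      degree = rowSums(A),
      A_norm = normalize_adjacency(A, add_self_loops),
      X = X,
      threshold = threshold,
      R = R
    ),
    class = "sample_graph"
  )
}

#' @export
print.sample_graph <- function(x, ...) {
  n <- length(x$node_ids)
  cat(sprintf(
    "<sample_graph> %d nodes, %d edges (threshold %.3g), %d features/node\n",
    n, sum(x$A) / 2, x$threshold, ncol(x$X)
  ))
  invisible(x)
}

#' Export graph edges as TSV (`source_id`, `target_id`, `correlation`)
#' @param graph a [sample_graph()].
#' @param path output file path.
#' @export
export_edge_list <- function(graph, path) {
  idx <- which(upper.tri(graph$A) & graph$A == 1, arr.ind = TRUE)
  df <- data.frame(
    source_id = graph$node_ids[idx[, 1]],
    target_id = graph$node_ids[idx[, 2]],
    correlation = graph$R[idx]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-import an edge-list TSV as a binary adjacency matrix
#' @param path edge-list TSV written by [export_edge_list()].
#' @param node_ids full node identifier vector (isolated nodes carry no
#'   edges, so the list alone cannot recover them).
#' @return binary adjacency matrix over `node_ids`.
#' @export
import_edge_list <- function(path, node_ids) {
  df <- utils::read.delim(path)
  n <- length(node_ids)
  A <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  if (nrow(df)) {
    i <- match(df$source_id, node_ids)
    j <- match(df$target_id, node_ids)
    if (anyNA(i) || anyNA(j)) stop("edge list references unknown node ids")
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Export a sample graph as GraphML for external inspection
#'
#' Requires the suggested igraph package.
#' @param graph a [sample_graph()].
#' @param path output file path.
#' @export
export_graphml <- function(graph, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export needs the 'igraph' package")
  }
  g <- igraph::graph_from_adjacency_matrix(graph$A, mode = "undirected")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
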