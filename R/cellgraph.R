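#' Build the k-nearest-neighbour cell graph
#'
#' Each cell is linked to its k nearest other cells by Euclidean distance
#' (ties broken by ascending cell index, self excluded); the directed
#' relation is then symmetrized by union, so `A[i, j] == 1` iff j is among
#' i's k nearest or i is among j's k nearest. k is clamped to N - 1 when it
#' exceeds it, and a single-cell pattern yields the 1 x 1 zero adjacency.
#'
#' The returned graph carries the self-looped adjacency `A_hat = A + I`,
#' its degree vector `D_hat` and the symmetrically normalized propagation
#' operator `A_tilde = D_hat^(-1/2) A_hat D_hat^(-1/2)` used by the graph
#' convolution.
#'
#' @param pattern a `point_pattern`, or a bare N x 2 coordinate matrix.
#' @param k positive integer neighbour count (default 20).
#' @return An object of class `"cell_graph"`: list with `n_cells`, `k`
#'   (the clamped value used), sparse matrices `A`, `A_hat`, `A_tilde`
#'   (`Matrix::dgCMatrix`) and numeric `D_hat`.
#' @export
build_knn_adjacency <- function(pattern, k = 20L) {
  coords <- if (inherits(pattern, "point_pattern")) pattern$coords
            else as.matrix(pattern)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (n < 1) stop("need at least one cell")
  if (k < 1) stop("k must be >= 1")
  k_eff <- min(as.integer(k), n - 1L)
  if (n == 1L) {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(1, 1))
    g <- structure(list(n_cells = 1L, k = 0L, A = A), class = "cell_graph")
    return(normalize_adjacency(g))
  }
  d2 <- as.matrix(stats::dist(coords))
  diag(d2) <- Inf
  # order() is stable: equal distances resolve to the lower cell index
  nn <- t(apply(d2, 1L, function(row) order(row)[seq_len(k_eff)]))
  ii <- rep(seq_len(n), each = k_eff)
  jj <- as.integer(t(nn))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A <- methods::as(((A + Matrix::t(A)) > 0) * 1, "CsparseMatrix")
  g <- structure(list(n_cells = n, k = k_eff, A = A), class = "cell_graph")
  normalize_adjacency(g)
}

#' Symmetrically normalize a cell-graph adjacency
#'
#' Computes `A_hat = A + I`, the degree vector `D_hat[i] = 1 + rowsum(A)[i]`
#' and `A_tilde` with entries `A_hat[i, j] / sqrt(D_hat[i] * D_hat[j])`,
#' storing all three back on the graph.
#'
#' @param graph a `cell_graph` with a valid binary symmetric `A`.
#' @return The graph with `A_hat`, `D_hat`, `A_tilde` filled in.
#' @export
normalize_adjacency <- function(graph) {
  n <- graph$n_cells
  A_hat <- graph$A + Matrix::Diagonal(n)
  D_hat <- as.numeric(Matrix::rowSums(A_hat))
  inv_sqrt <- 1 / sqrt(D_hat)
  A_tilde <- Matrix::Diagonal(n, inv_sqrt) %*% A_hat %*%
    Matrix::Diagonal(n, inv_sqrt)
  graph$A_hat <- methods::as(A_hat, "CsparseMatrix")
  graph$D_hat <- D_hat
  graph$A_tilde <- methods::as(A_tilde, "CsparseMatrix")
  graph
}

#' @export
print.cell_graph <- function(x, ...) {
  m <- Matrix::nnzero(x$A) / 2
  cat("Cell graph: ", x$n_cells, " cells, k = ", x$k, ", ",
      m, " undirected edges\n", sep = "")
  invisible(x)
}

#' Export the undirected edge list of a cell graph
#'
#' @param graph a `cell_graph`.
#' @param zero_based logical; if `TRUE` (default) indices start at 0 for
#'   interoperability with plotting tools.
#' @return Two-column integer matrix (`from`, `to`), one row per
#'   undirected edge with `from < to`.
#' @export
edge_list <- function(graph, zero_based = TRUE) {
  tri <- Matrix::which(Matrix::triu(graph$A, k = 1) != 0, arr.ind = TRUE)
  el <- matrix(as.integer(tri), ncol = 2,
               dimnames = list(NULL, c("from", "to")))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  if (zero_based) el <- el - 1L
  el
}
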