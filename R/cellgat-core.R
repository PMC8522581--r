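#' Model configuration for a cell-graph attention network
#'
#' Defaults follow the reference hyper-parameterization for pancreatic
#' mIF point patterns: embedding dimension d = 30, l = 2 graph-convolution
#' layers, k = 20 nearest neighbours, ReLU activation.
#'
#' @param d embedding dimension.
#' @param l number of GCN layers.
#' @param k neighbour count for the cell graph.
#' @param cell_types label dictionary (its length is the embedding
#'   vocabulary size V).
#' @param activation `"relu"` or `"tanh"`, applied elementwise in each GCN
#'   layer.
#' @param seed integer seed governing parameter initialization and epoch
#'   shuffling.
#' @return List of class `"cellgat_config"`.
#' @export
cellgat_config <- function(d = 30L, l = 2L, k = 20L,
                           cell_types = default_cell_types(),
                           activation = c("relu", "tanh"), seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(d >= 1, l >= 1, k >= 1, length(cell_types) >= 2)
  structure(list(d = as.integer(d), l = as.integer(l), k = as.integer(k),
                 cell_types = as.character(cell_types),
                 vocab = length(cell_types), activation = activation,
                 seed = as.integer(seed)),
            class = "cellgat_config")
}

#' Initialize trainable parameters
#'
#' Small-scale random normal initialization (sd 0.1), seeded. Parameters:
#' a V x d embedding table, l d x d GCN weight matrices, the length-d
#' attention vector w, and a d x 2 affine output head with bias.
#'
#' @param config a `cellgat_config`.
#' @param sd initialization scale.
#' @return List of class `"cellgat_params"`.
#' @export
init_cellgat_params <- function(config, sd = 0.1) {
  set.seed(config$seed)
  d <- config$d
  structure(list(
    embedding = matrix(stats::rnorm(config$vocab * d, sd = sd),
                       config$vocab, d,
                       dimnames = list(config$cell_types, NULL)),
    gcn = lapply(seq_len(config$l),
                 function(t) matrix(stats::rnorm(d * d, sd = sd), d, d)),
    attn_w = stats::rnorm(d, sd = sd),
    ffn_W = matrix(stats::rnorm(d * 2, sd = sd), d, 2),
    ffn_b = stats::rnorm(2, sd = sd)),
    class = "cellgat_params")
}

#' Embed symbolic cell-type labels
#'
#' Looks each label up in the trainable embedding table, producing the
#' initial node-feature matrix X0 (row i = table row for label i).
#'
#' @param labels factor or character vector of cell types.
#' @param params a `cellgat_params` (or any list with an `embedding`
#'   matrix whose rownames are the dictionary).
#' @return N x d numeric matrix.
#' @export
embed_labels <- function(labels, params) {
  tab <- params$embedding
  idx <- if (is.factor(labels)) as.integer(labels)
         else match(as.character(labels), rownames(tab))
  if (anyNA(idx) || any(idx > nrow(tab)))
    stop("label outside the embedding dictionary")
  tab[idx, , drop = FALSE]
}

#' One graph-convolution layer
#'
#' Computes `sigma(A_tilde %*% X %*% W)` with the activation applied
#' elementwise — the message-passing update that mixes each cell's feature
#' with its (degree-normalized) neighbourhood.
#'
#' @param X N x d node-feature matrix.
#' @param A_tilde N x N normalized adjacency.
#' @param W d x d weight matrix.
#' @param activation `"relu"` or `"tanh"`.
#' @return N x d matrix of updated node features.
#' @export
gcn_layer <- function(X, A_tilde, W, activation = "relu") {
  if (nrow(X) != nrow(A_tilde) || ncol(X) != nrow(W))
    stop("shape mismatch in GCN layer")
  Z <- as.matrix(A_tilde %*% X) %*% W
  switch(activation,
         relu = pmax(Z, 0),
         tanh = tanh(Z),
         stop("unknown activation: ", activation))
}

#' Self-attention read-out
#'
#' Scores each cell with `alpha = tanh(X) %*% w`, soft-maxes the scores to
#' simplex weights p (max-subtraction for numerical stability) and pools
#' the node embeddings into the fixed-dimension context vector
#' `s = t(X) %*% p`. The context vector has length d regardless of the
#' number of cells, which is what lets graphs of different sizes share one
#' classifier head; p is the per-cell importance used for interpretation.
#'
#' @param X N x d final node-embedding matrix.
#' @param w length-d attention parameter.
#' @return Object of class `"attention_result"`: list with `alpha`
#'   (length N), `p` (length N, on the simplex) and `s` (length d).
#' @export
self_attention <- function(X, w) {
  X <- as.matrix(X)
  if (ncol(X) != length(w)) stop("attention vector length must equal d")
  alpha <- as.numeric(tanh(X) %*% w)
  e <- exp(alpha - max(alpha))
  p <- e / sum(e)
  s <- as.numeric(crossprod(X, p))
  structure(list(alpha = alpha, p = p, s = s), class = "attention_result")
}

#' @export
print.attention_result <- function(x, ...) {
  cat("Attention read-out over", length(x$p), "cells; context dim",
      length(x$s), "\n")
  cat("top-5 weights:",
      paste(signif(sort(x$p, decreasing = TRUE)[seq_len(min(5, length(x$p)))],
                   4), collapse = " "), "\n")
  invisible(x)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Forward pass of the cell-graph attention network
#'
#' Pipeline: k-NN graph construction, adjacency normalization, label
#' embedding, l graph-convolution layers, self-attention read-out, affine
#' map d -> 2 and soft-max.
#'
#' @param pattern a `point_pattern`.
#' @param params a `cellgat_params`.
#' @param config a `cellgat_config`.
#' @param graph optional precomputed `cell_graph` (the graph depends only
#'   on the coordinates, so callers training over epochs cache it).
#' @return List with `prob` (length-2 class probabilities, summing to 1)
#'   and `attention` (an `attention_result`).
#' @export
cellgat_forward <- function(pattern, params, config, graph = NULL) {
  if (is.null(graph)) graph <- build_knn_adjacency(pattern, config$k)
  X <- embed_labels(pattern$labels, params)
  for (t in seq_len(config$l))
    X <- gcn_layer(X, graph$A_tilde, params$gcn[[t]], config$activation)
  att <- self_attention(X, params$attn_w)
  z <- as.numeric(crossprod(params$ffn_W, att$s)) + params$ffn_b
  list(prob = softmax(z), attention = att)
}

#' Select cells above an attention percentile
#'
#' Returns the indices of cells whose attention weight p is at or above
#' the q-th percentile of p (linear-interpolation percentile, inclusive
#' threshold — so fully tied weights select every cell).
#'
#' @param att an `attention_result` (or any list with a numeric `p`).
#' @param q percentile in \[0, 100\]; 90 highlights the top decile, 50 the
#'   top half.
#' @return Integer vector of selected cell indices (1-based).
#' @export
attention_percentile_mask <- function(att, q) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0 || q > 100)
    stop("percentile q must be a single value in [0, 100]")
  p <- att$p
  thr <- as.numeric(stats::quantile(p, q / 100, type = 7, names = FALSE))
  which(p >= thr)
}
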