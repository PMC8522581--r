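# Shared fixtures: random patterns and brute-force oracles kept
# independent of the package's own linear-algebra paths.

rand_pattern <- function(n, seed = 1, types = default_cell_types(),
                         extent = 100) {
  set.seed(seed)
  point_pattern(matrix(stats::runif(2 * n, 0, extent), n, 2),
                sample(types, n, replace = TRUE),
                sample_id = paste0("rp", seed))
}

# all-pairs union-symmetrized k-NN adjacency, one pair at a time
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  k <- min(k, n - 1)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], n, 2, byrow = TRUE))^2))
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    A[i, nb] <- 1
  }
  pmax(A, t(A))
}

# entry-by-entry normalized adjacency
brute_norm_adj <- function(A) {
  n <- nrow(A)
  Ah <- A + diag(n)
  Dh <- rowSums(Ah)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- Ah[i, j] / sqrt(Dh[i] * Dh[j])
  out
}

# per-node GCN layer: weighted neighbour sum, then weights, then activation
brute_gcn <- function(X, At, W, activation = "relu") {
  n <- nrow(X)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    agg <- rep(0, ncol(X))
    for (j in seq_len(n)) agg <- agg + At[i, j] * X[j, ]
    z <- as.numeric(agg %*% W)
    out[i, ] <- if (activation == "relu") pmax(z, 0) else tanh(z)
  }
  out
}

# single-label patterns for the separable-by-embedding training check
mono_pattern <- function(lab, seed, cls, n = 40) {
  set.seed(seed)
  point_pattern(matrix(stats::runif(2 * n, 0, 100), n, 2), rep(lab, n),
                sample_id = paste0(cls, "_", seed), disease_class = cls)
}
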