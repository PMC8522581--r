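#' Build the 3-nearest-neighbour graph used for enrichment analysis
#'
#' Neighbourhood enrichment operates on a sparser graph than the
#' classifier: each cell is linked to its three nearest neighbours
#' (union-symmetrized, k clamped to N - 1 for tiny samples).
#'
#' @param pattern a `point_pattern` with at least 2 cells.
#' @param k neighbour count (default 3).
#' @return A `cell_graph`.
#' @export
build_neighbor_graph <- function(pattern, k = 3L) {
  if (n_cells(pattern) < 2)
    stop("neighbourhood analysis needs at least 2 cells")
  build_knn_adjacency(pattern, k = k)
}

#' Cell-type pair enrichment by label permutation
#'
#' For every unordered cell-type pair (same-type pairs included) the
#' number of graph edges joining the two types is compared to a null
#' distribution obtained by shuffling the cell-type labels across nodes
#' while keeping the graph topology fixed. A pair whose observed edge
#' count is significantly higher than the null is "enriched" (the two
#' types neighbour each other more than expected at random); significantly
#' lower is "depleted". P-values use the add-one pseudocount
#' `p = (1 + #(null >= obs)) / (1 + n_perm)` (and `<=` for depletion) so
#' they are never zero.
#'
#' @param graph a `cell_graph` (typically from [build_neighbor_graph()]).
#' @param labels cell-type labels, one per node.
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed; results are reproducible field-for-field.
#' @param alpha significance level for the enriched/depleted call
#'   (default 0.05).
#' @param cell_types dictionary defining the pairs reported; defaults to
#'   the levels of `labels` or [default_cell_types()].
#' @return data.frame of class `"enrichment_result"`, one row per
#'   unordered type pair: `type_a`, `type_b`, `observed`, `null_mean`,
#'   `null_sd`, `z`, `p_enrich`, `p_deplete`, `call`, plus attributes
#'   `n_perm` and `seed`.
#' @export
permutation_enrichment <- function(graph, labels, n_perm = 999L, seed = 1L,
                                   alpha = 0.05, cell_types = NULL) {
  n <- graph$n_cells
  if (length(labels) != n)
    stop("labels length (", length(labels),
         ") does not match graph size (", n, ")")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(cell_types))
    cell_types <- if (is.factor(labels)) levels(labels)
                  else sort(unique(as.character(labels)))
  lab <- match(as.character(labels), cell_types)
  if (anyNA(lab)) stop("labels outside the declared cell-type set")
  V <- length(cell_types)

  el <- edge_list(graph, zero_based = FALSE)
  # unordered pair id for an edge with endpoint types a <= b
  pid <- function(l1, l2) {
    a <- pmin(l1, l2); b <- pmax(l1, l2)
    (a - 1L) * V - ((a - 1L) * (a - 2L)) %/% 2L + b - a + 1L
  }
  npair <- (V * (V + 1L)) %/% 2L
  obs <- tabulate(pid(lab[el[, 1]], lab[el[, 2]]), npair)

  set.seed(seed)
  null_counts <- matrix(0L, n_perm, npair)
  for (r in seq_len(n_perm)) {
    pl <- lab[sample.int(n)]
    null_counts[r, ] <- tabulate(pid(pl[el[, 1]], pl[el[, 2]]), npair)
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2, stats::sd)
  z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, 0)
  p_enr <- (1 + colSums(null_counts >= rep(obs, each = n_perm))) /
    (1 + n_perm)
  p_dep <- (1 + colSums(null_counts <= rep(obs, each = n_perm))) /
    (1 + n_perm)
  call <- ifelse(p_enr < alpha, "enriched",
                 ifelse(p_dep < alpha, "depleted", "neutral"))

  idx <- which(upper.tri(matrix(0, V, V), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(type_a = cell_types[idx[, 1]],
                    type_b = cell_types[idx[, 2]],
                    observed = obs, null_mean = null_mean,
                    null_sd = null_sd, z = z,
                    p_enrich = p_enr, p_deplete = p_dep, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment within the high-attention cell subset
#'
#' Restricts a sample to the cells at or above the q-th attention
#' percentile (see [attention_percentile_mask()]), rebuilds the 3-NN
#' graph on that subset alone, and runs the permutation enrichment there.
#' Interrogating only the cells the classifier attends to asks which
#' type-type adjacencies characterize the regions driving the prediction.
#'
#' @param pattern a `point_pattern`.
#' @param att the sample's `attention_result` (e.g. from
#'   `predict(model, pattern, type = "attention")`).
#' @param q attention percentile (default 50: the top half of cells).
#' @param n_perm,seed,alpha passed to [permutation_enrichment()].
#' @return An `enrichment_result`; errors informatively when the subset
#'   has fewer than 2 cells.
#' @export
attention_subset_enrichment <- function(pattern, att, q = 50,
                                        n_perm = 999L, seed = 1L,
                                        alpha = 0.05) {
  sel <- attention_percentile_mask(att, q)
  if (length(sel) < 2)
    stop("attention subset at percentile ", q, " has ", length(sel),
         " cell(s); need at least 2 for a neighbour graph")
  sub <- point_pattern(pattern$coords[sel, , drop = FALSE],
                       as.character(pattern$labels)[sel],
                       sample_id = paste0(pattern$sample_id, "_attn", q),
                       cell_types = pattern$cell_types,
                       disease_class = pattern$disease_class)
  g <- build_neighbor_graph(sub)
  permutation_enrichment(g, sub$labels, n_perm = n_perm, seed = seed,
                         alpha = alpha, cell_types = pattern$cell_types)
}
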