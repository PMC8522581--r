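test_that("neighbour graph uses 3-NN with clamping", {
  pp <- rand_pattern(4, seed = 1)
  g <- build_neighbor_graph(pp)
  expect_true(all(Matrix::rowSums(g$A) >= 3))
  two <- point_pattern(rbind(c(0, 0), c(1, 1)), c("CTL", "Treg"))
  g2 <- build_neighbor_graph(two)
  expect_equal(Matrix::nnzero(g2$A) / 2, 1)
  expect_error(build_neighbor_graph(point_pattern(matrix(0, 1, 2), "CTL")),
               "at least 2")

  # collinear points: edges agree with all-pairs distance ranking
  line <- point_pattern(cbind(c(0, 1, 2, 3, 4) * 10, 0), rep("CTL", 5))
  g5 <- build_neighbor_graph(line)
  expect_equal(as.matrix(g5$A), brute_knn(line$coords, 3))
})

test_that("a single label makes every pair count permutation invariant", {
  pp <- point_pattern(matrix(runif(60), 30, 2), rep("CTL", 30),
                      cell_types = c("CTL", "Treg"))
  g <- build_neighbor_graph(pp)
  er <- permutation_enrichment(g, pp$labels, n_perm = 99, seed = 1)
  row <- er[er$type_a == "CTL" & er$type_b == "CTL", ]
  expect_equal(row$observed, Matrix::nnzero(g$A) / 2)
  expect_equal(row$p_enrich, 1)
  expect_equal(row$p_deplete, 1)
  expect_equal(row$call, "neutral")
})

test_that("distant single-type clusters deplete the cross-type pair", {
  set.seed(3)
  pp <- point_pattern(
    rbind(cbind(rnorm(40), rnorm(40)), cbind(rnorm(40) + 1000, rnorm(40))),
    c(rep("Epithelial", 40), rep("CTL", 40)))
  g <- build_neighbor_graph(pp)
  er <- permutation_enrichment(g, pp$labels, n_perm = 999, seed = 7,
                               alpha = 0.05)
  cross <- er[er$type_a == "Epithelial" & er$type_b == "CTL", ]
  expect_equal(cross$observed, 0)
  expect_gt(cross$null_mean, 0)
  expect_lt(cross$p_deplete, 0.05)
  expect_equal(cross$call, "depleted")
  same <- er[er$type_a == "Epithelial" & er$type_b == "Epithelial", ]
  expect_equal(same$call, "enriched")
})

test_that("enrichment is reproducible field-for-field and conserves edges", {
  pp <- rand_pattern(80, seed = 12)
  g <- build_neighbor_graph(pp)
  e1 <- permutation_enrichment(g, pp$labels, n_perm = 199, seed = 5)
  e2 <- permutation_enrichment(g, pp$labels, n_perm = 199, seed = 5)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_equal(sum(e1$observed), Matrix::nnzero(g$A) / 2)
  # p-values keep the add-one pseudocount bounds
  expect_true(all(e1$p_enrich > 0 & e1$p_enrich <= 1))
  expect_true(all(e1$p_deplete >= 1 / 200))
  expect_error(permutation_enrichment(g, pp$labels[-1], 99, 1), "match")
})

test_that("adding a cross-type edge never decreases its observed count", {
  pp <- rand_pattern(30, seed = 9)
  g <- build_neighbor_graph(pp)
  er <- permutation_enrichment(g, pp$labels, n_perm = 49, seed = 2)
  lab <- as.character(pp$labels)
  # find a currently unlinked Epithelial-CTL node pair and connect it
  ep <- which(lab == "Epithelial"); ct <- which(lab == "CTL")
  A <- as.matrix(g$A)
  found <- FALSE
  for (i in ep) {
    js <- ct[A[i, ct] == 0]
    if (length(js)) { j <- js[1]; found <- TRUE; break }
  }
  expect_true(found)   # 3-NN graph on 30 cells is far from complete
  g$A[i, j] <- g$A[j, i] <- 1
  g <- normalize_adjacency(g)
  er2 <- permutation_enrichment(g, pp$labels, n_perm = 49, seed = 2)
  pick <- function(e) e$observed[e$type_a == "CTL" & e$type_b == "Epithelial" |
                                   e$type_a == "Epithelial" & e$type_b == "CTL"]
  expect_equal(pick(er2), pick(er) + 1)
})

test_that("attention-subset enrichment masks, rebuilds and errors usefully", {
  pp <- rand_pattern(60, seed = 15)
  p_distinct <- (1:60) / sum(1:60)
  att <- structure(list(alpha = p_distinct, p = p_distinct),
                   class = "attention_result")
  # q = 0 keeps every cell: identical to the full-sample analysis
  full <- permutation_enrichment(build_neighbor_graph(pp), pp$labels,
                                 n_perm = 99, seed = 3)
  sub0 <- attention_subset_enrichment(pp, att, q = 0, n_perm = 99, seed = 3)
  expect_equal(sub0$observed, full$observed)
  expect_equal(sub0$p_enrich, full$p_enrich)
  # q = 100 with distinct weights leaves one cell: informative error
  expect_error(attention_subset_enrichment(pp, att, q = 100), "at least 2")
})

test_that("a mixed high-attention interface enriches the cross pair there", {
  # two pure distant blocks plus a tight mixed interface in between
  set.seed(30)
  block_a <- cbind(rnorm(40, 0, 5), rnorm(40, 0, 5))
  block_b <- cbind(rnorm(40, 400, 5), rnorm(40, 0, 5))
  interf <- cbind(rnorm(40, 200, 3), rnorm(40, 0, 3))
  pp <- point_pattern(rbind(block_a, block_b, interf),
                      c(rep("Epithelial", 40), rep("Treg", 40),
                        rep("Epithelial", 20), rep("Treg", 20)))
  # stubbed attention concentrated on the interface cells
  p <- c(rep(1, 80), rep(100, 40)); p <- p / sum(p)
  att <- structure(list(alpha = p, p = p), class = "attention_result")
  sub <- attention_subset_enrichment(pp, att, q = 100 * 80 / 120,
                                     n_perm = 499, seed = 8)
  cross <- sub[sub$type_a == "Epithelial" & sub$type_b == "Treg", ]
  full <- permutation_enrichment(build_neighbor_graph(pp), pp$labels,
                                 n_perm = 499, seed = 8)
  fcross <- full[full$type_a == "Epithelial" & full$type_b == "Treg", ]
  # globally the segregated blocks deplete the pair; on the attended
  # interface the two types are thoroughly mixed
  expect_equal(fcross$call, "depleted")
  expect_gt(cross$z, fcross$z)
  expect_equal(cross$call, "neutral")   # mixing matches the shuffled null
})
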