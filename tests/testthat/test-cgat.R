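test_that("label embedding is a pure table lookup", {
  cfg <- cellgat_config(d = 4, seed = 3)
  params <- init_cellgat_params(cfg)
  X <- embed_labels(c("Epithelial", "CTL", "Epithelial"), params)
  expect_equal(X[1, ], X[3, ])
  expect_equal(X[2, ], params$embedding["CTL", ])
  expect_equal(embed_labels(rep("Treg", 5), params),
               params$embedding[rep(3, 5), ])
  params$embedding[] <- 0
  expect_equal(embed_labels(c("CTL", "Treg"), params), matrix(0, 2, 4),
               ignore_attr = TRUE)
  expect_error(embed_labels("Bcell", params), "dictionary")
})

test_that("GCN layer equals its closed-form micro examples", {
  # zero weights give zero output under both activations
  X <- matrix(rnorm(12), 4, 3)
  At <- diag(4)
  expect_equal(gcn_layer(X, At, matrix(0, 3, 3), "relu"), matrix(0, 4, 3))
  expect_equal(gcn_layer(X, At, matrix(0, 3, 3), "tanh"), matrix(0, 4, 3))

  # isolated node, identity weight, relu clamps negatives
  expect_equal(gcn_layer(matrix(c(-1, 2), 1, 2), matrix(1, 1, 1),
                         diag(2), "relu"),
               matrix(c(0, 2), 1, 2))

  # two connected nodes average their features through A_tilde = 0.5
  g <- build_knn_adjacency(rbind(c(0, 0), c(1, 0)), k = 1)
  out <- gcn_layer(rbind(c(1, 0), c(0, 1)), g$A_tilde, diag(2), "relu")
  expect_equal(out, matrix(0.5, 2, 2))

  expect_error(gcn_layer(X, diag(3), diag(3)), "shape")
})

test_that("GCN layer matches the per-node brute-force oracle", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(2:25, 1); d <- sample(2:6, 1)
    g <- build_knn_adjacency(rand_pattern(n, seed = 300 + s), sample(1:4, 1))
    X <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(d * d), d, d)
    act <- sample(c("relu", "tanh"), 1)
    expect_lt(max(abs(gcn_layer(X, g$A_tilde, W, act) -
                        brute_gcn(X, as.matrix(g$A_tilde), W, act))), 1e-10)
  }
})

test_that("self-attention follows the read-out rules", {
  # zero attention vector: uniform weights, s = column means
  X <- matrix(rnorm(15), 5, 3)
  att <- self_attention(X, rep(0, 3))
  expect_equal(att$p, rep(0.2, 5))
  expect_equal(att$s, colMeans(X))

  # single cell: p = 1, s = the row itself
  a1 <- self_attention(matrix(1:3, 1, 3), rnorm(3))
  expect_equal(a1$p, 1)
  expect_equal(a1$s, c(1, 2, 3))

  # scalar oracle: alpha = tanh(X) w, soft-max, weighted pooling
  a2 <- self_attention(matrix(c(0, 10), 2, 1), 1)
  expect_equal(a2$alpha, c(0, tanh(10)))
  expect_equal(a2$p, c(0.2689, 0.7311), tolerance = 1e-4)
  expect_equal(a2$s, 10 * a2$p[2])
})

test_that("attention weights stay on the simplex and s = t(X) p", {
  for (s in 1:1000) {
    set.seed(s)
    n <- sample(1:20, 1); d <- sample(1:5, 1)
    X <- matrix(rnorm(n * d, sd = sample(c(0.1, 1, 50), 1)), n, d)
    att <- self_attention(X, rnorm(d))
    expect_true(all(att$p >= 0))
    expect_lt(abs(sum(att$p) - 1), 1e-9)
    expect_lt(max(abs(att$s - as.numeric(crossprod(X, att$p)))), 1e-9)
  }
})

test_that("forward pass yields probabilities and permutation invariance", {
  cfg <- cellgat_config(d = 6, l = 2, k = 4, seed = 11)
  params <- init_cellgat_params(cfg)
  pp <- rand_pattern(30, seed = 5)

  # all-zero parameters: soft-max of (0, 0)
  z <- params
  z$embedding[] <- 0; z$attn_w[] <- 0; z$ffn_W[] <- 0; z$ffn_b[] <- 0
  for (t in seq_along(z$gcn)) z$gcn[[t]][] <- 0
  expect_equal(cellgat_forward(pp, z, cfg)$prob, c(0.5, 0.5))

  out <- cellgat_forward(pp, params, cfg)
  expect_lt(abs(sum(out$prob) - 1), 1e-9)

  for (s in 1:10) {
    set.seed(s)
    perm <- sample.int(30)
    pp2 <- point_pattern(pp$coords[perm, ], as.character(pp$labels)[perm])
    out2 <- cellgat_forward(pp2, params, cfg)
    expect_lt(max(abs(out2$prob - out$prob)), 1e-6)
    expect_lt(max(abs(out2$attention$p - out$attention$p[perm])), 1e-6)
  }
})

test_that("context vector dimension is independent of cell count", {
  cfg <- cellgat_config(d = 30, seed = 2)
  params <- init_cellgat_params(cfg)
  for (n in c(1, 5, 50, 500)) {
    out <- cellgat_forward(rand_pattern(n, seed = n), params, cfg)
    expect_length(out$attention$s, 30)
    expect_length(out$prob, 2)
  }
})

test_that("attention percentile mask uses an inclusive interpolated threshold", {
  uni <- structure(list(p = rep(0.1, 10)), class = "attention_result")
  expect_equal(attention_percentile_mask(uni, 90), 1:10)   # full tie
  expect_equal(attention_percentile_mask(uni, 0), 1:10)

  ps <- (1:10) / sum(1:10)
  att <- structure(list(p = ps), class = "attention_result")
  expect_equal(attention_percentile_mask(att, 90), 10L)    # top cell only
  expect_equal(attention_percentile_mask(att, 0), 1:10)
  expect_setequal(attention_percentile_mask(att, 50), 6:10)
  expect_error(attention_percentile_mask(att, 101), "\\[0, 100\\]")
  expect_error(attention_percentile_mask(att, -1), "\\[0, 100\\]")
})

test_that("training separates embedding-distinguishable classes", {
  cohort <- c(lapply(1:10, function(i) mono_pattern("Epithelial", i, "A")),
              lapply(11:20, function(i) mono_pattern("CTL", i, "B")))
  cfg <- cellgat_config(seed = 1)
  fit <- cellgat(cohort, classes = c("A", "B"), config = cfg, epochs = 100)
  expect_lt(utils::tail(fit$loss_trace, 1), 0.1)
  expect_lt(utils::tail(fit$loss_trace, 1), fit$loss_trace[1])

  # seeded determinism: identical refit
  fit2 <- cellgat(cohort, classes = c("A", "B"), config = cfg, epochs = 100)
  expect_equal(utils::tail(fit$loss_trace, 1),
               utils::tail(fit2$loss_trace, 1), tolerance = 1e-12)
  expect_equal(fit$params$attn_w, fit2$params$attn_w)

  # prediction API
  pr <- predict(fit, cohort, type = "prob")
  expect_equal(dim(pr), c(20, 2))
  expect_equal(colnames(pr), c("A", "B"))
  expect_equal(predict(fit, cohort, type = "class"),
               rep(c("A", "B"), each = 10))
  expect_error(cellgat(cohort[1:10], classes = c("A", "B")), "each class")
})

test_that("checkpoints round-trip through JSON", {
  cohort <- c(lapply(1:3, function(i) mono_pattern("Epithelial", i, "A", 15)),
              lapply(4:6, function(i) mono_pattern("Treg", i, "B", 15)))
  fit <- cellgat(cohort, classes = c("A", "B"),
                 config = cellgat_config(d = 7, seed = 5), epochs = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_cellgat_checkpoint(fit, f)
  back <- read_cellgat_checkpoint(f)
  expect_equal(back$params, fit$params, tolerance = 1e-12)
  expect_equal(back$classes, fit$classes)
  pp <- rand_pattern(25, seed = 77)
  expect_equal(predict(back, pp, type = "prob"),
               predict(fit, pp, type = "prob"), tolerance = 1e-12)
})

test_that("attention table flags the selected percentile", {
  pp <- rand_pattern(40, seed = 9)
  fit_cfg <- cellgat_config(d = 5, seed = 4)
  params <- init_cellgat_params(fit_cfg)
  att <- cellgat_forward(pp, params, fit_cfg)$attention
  tab <- attention_table(pp, att, q = 90)
  expect_equal(nrow(tab), 40)
  expect_equal(sum(tab$selected), length(attention_percentile_mask(att, 90)))
  expect_equal(tab$p, att$p)
})
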