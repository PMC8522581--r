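#' Fit a pairwise cell-graph attention classifier
#'
#' Trains the full network — label-embedding table, the l GCN weight
#' matrices, the attention vector and the affine soft-max head — jointly
#' end-to-end by cross-entropy gradient descent with an Adam optimizer,
#' one graph per optimization step. An epoch is one pass over the training
#' samples in a freshly shuffled (seeded) order. Cell graphs depend only
#' on the coordinates, so they are built once per sample and cached across
#' epochs.
#'
#' @param cohort list of `point_pattern`s, each with `disease_class` set.
#' @param classes length-2 character vector `(positive, negative)`; the
#'   first column of predicted probabilities refers to the positive class.
#'   Defaults to the two classes present in `cohort`.
#' @param config a [cellgat_config()].
#' @param epochs number of passes over the training set (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param class_weights if `TRUE`, weight each sample's loss inversely to
#'   its class frequency. Off by default: class imbalance is handled at
#'   the consensus level by combining pairwise classifiers, not by loss
#'   reweighting.
#' @param verbose print the loss every 10 epochs.
#' @return Object of class `"cellgat"`: the fitted parameters plus config,
#'   class pair, per-epoch mean training loss (`loss_trace`), epochs run
#'   and seed.
#' @seealso [predict.cellgat()], [cellgat_consensus()]
#' @export
cellgat <- function(cohort, classes = NULL, config = cellgat_config(),
                    epochs = 100L, lr = 1e-3, class_weights = FALSE,
                    verbose = FALSE) {
  y_all <- vapply(cohort, function(p) p$disease_class, character(1))
  if (is.null(classes)) classes <- sort(unique(y_all))
  if (length(classes) != 2 || classes[1] == classes[2])
    stop("'classes' must name two distinct disease classes")
  keep <- y_all %in% classes
  cohort <- cohort[keep]
  y <- match(y_all[keep], classes)          # 1 = positive, 2 = negative
  if (!all(1:2 %in% y))
    stop("cohort must contain at least one sample of each class (",
         paste(classes, collapse = ", "), ")")
  m <- length(cohort)
  wts <- if (class_weights) (m / (2 * tabulate(y, 2)))[y] else rep(1, m)

  params <- init_cellgat_params(config)     # seeds the RNG stream
  graphs <- lapply(cohort, build_knn_adjacency, k = config$k)
  lab_idx <- lapply(cohort, function(p) as.integer(p$labels))

  opt <- adam_state(params, lr = lr)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(m)
    tot <- 0
    for (i in ord) {
      fb <- cellgat_loss_grad(lab_idx[[i]], graphs[[i]]$A_tilde,
                              y[i], params, config)
      if (!is.finite(fb$loss))
        stop("non-finite training loss at epoch ", ep, ", sample ",
             cohort[[i]]$sample_id, "; try a smaller learning rate")
      if (wts[i] != 1) fb$grad <- rapply(fb$grad, function(g) g * wts[i],
                                         how = "replace")
      opt <- adam_step(opt, fb$grad)
      params <- opt$params
      tot <- tot + wts[i] * fb$loss
    }
    loss_trace[ep] <- tot / sum(wts)
    if (verbose && ep %% 10 == 0)
      cat(sprintf("epoch %3d  loss %.4f\n", ep, loss_trace[ep]))
  }

  structure(list(params = params, config = config, classes = classes,
                 loss_trace = loss_trace, epochs = epochs, lr = lr,
                 seed = config$seed, n_train = m),
            class = "cellgat")
}

# Forward pass keeping intermediates, then reverse-mode gradients for one
# graph. Returns the cross-entropy loss and gradients matching the
# cellgat_params layout.
cellgat_loss_grad <- function(lab_idx, A_tilde, target, params, config) {
  l <- config$l
  Xs <- vector("list", l + 1)
  Hs <- vector("list", l)                   # H_t = A_tilde %*% X_{t-1}
  Xs[[1]] <- params$embedding[lab_idx, , drop = FALSE]
  for (t in seq_len(l)) {
    H <- as.matrix(A_tilde %*% Xs[[t]])
    Z <- H %*% params$gcn[[t]]
    Hs[[t]] <- H
    Xs[[t + 1]] <- if (config$activation == "relu") pmax(Z, 0) else tanh(Z)
  }
  Xl <- Xs[[l + 1]]
  Tl <- tanh(Xl)
  alpha <- as.numeric(Tl %*% params$attn_w)
  e <- exp(alpha - max(alpha))
  p <- e / sum(e)
  s <- as.numeric(crossprod(Xl, p))
  z <- as.numeric(crossprod(params$ffn_W, s)) + params$ffn_b
  lse <- max(z) + log(sum(exp(z - max(z))))
  loss <- lse - z[target]

  g_z <- exp(z - lse)
  g_z[target] <- g_z[target] - 1
  g_W_ffn <- s %o% g_z
  g_b_ffn <- g_z
  g_s <- as.numeric(params$ffn_W %*% g_z)
  g_Xl <- p %o% g_s
  g_p <- as.numeric(Xl %*% g_s)
  g_alpha <- p * (g_p - sum(p * g_p))
  g_Xl <- g_Xl + (g_alpha %o% params$attn_w) * (1 - Tl^2)
  g_w <- as.numeric(crossprod(Tl, g_alpha))

  g_gcn <- vector("list", l)
  g_X <- g_Xl
  for (t in rev(seq_len(l))) {
    g_M <- if (config$activation == "relu") g_X * (Xs[[t + 1]] > 0)
           else g_X * (1 - Xs[[t + 1]]^2)
    g_gcn[[t]] <- crossprod(Hs[[t]], g_M)
    g_X <- as.matrix(A_tilde %*% (g_M %*% t(params$gcn[[t]])))
  }
  g_emb <- matrix(0, nrow(params$embedding), ncol(params$embedding))
  acc <- rowsum(g_X, lab_idx)
  g_emb[as.integer(rownames(acc)), ] <- acc

  list(loss = loss,
       grad = list(embedding = g_emb, gcn = g_gcn, attn_w = g_w,
                   ffn_W = g_W_ffn, ffn_b = g_b_ffn))
}

# --- Adam over the nested parameter list --------------------------------

adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(params = params, m = zeros, v = zeros, t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(st, grad) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  upd <- function(p, m, v, g) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - st$lr * (m / c1) / (sqrt(v / c2) + st$eps)
    list(p, m, v)
  }
  walk <- function(p, m, v, g) {
    if (is.list(p)) {
      out <- Map(walk, p, m, v, g)
      list(lapply(out, `[[`, 1), lapply(out, `[[`, 2), lapply(out, `[[`, 3))
    } else upd(p, m, v, g)
  }
  res <- walk(unclass(st$params), st$m, st$v, grad)
  st$params <- structure(res[[1]], class = "cellgat_params")
  st$m <- res[[2]]
  st$v <- res[[3]]
  st
}

# --- S3 methods ---------------------------------------------------------

#' @export
print.cellgat <- function(x, ...) {
  cat("Cell-graph attention classifier: ", x$classes[1], " (positive) vs ",
      x$classes[2], "\n", sep = "")
  cat(sprintf("d = %d, l = %d layers, k = %d, activation = %s\n",
              x$config$d, x$config$l, x$config$k, x$config$activation))
  cat(sprintf("trained on %d graphs for %d epochs; final loss %.4f\n",
              x$n_train, x$epochs, utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.cellgat <- function(object, ...) {
  print(object)
  np <- sum(rapply(object$params, length, how = "unlist"))
  cat("trainable parameters:", np, "\n")
  cat(sprintf("loss: first epoch %.4f, last epoch %.4f\n",
              object$loss_trace[1], utils::tail(object$loss_trace, 1)))
  invisible(object)
}

#' @export
coef.cellgat <- function(object, ...) object$params

#' Plot the training-loss trace
#' @param x a fitted `cellgat`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cellgat <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "mean cross-entropy",
                 main = paste(x$classes, collapse = " vs "), ...)
  invisible(x)
}

#' Predict disease class for new point patterns
#'
#' @param object a fitted `cellgat`.
#' @param newdata a `point_pattern` or list of them.
#' @param type `"prob"` for the n x 2 probability matrix (columns named by
#'   the class pair), `"class"` for the arg-max labels, or `"attention"`
#'   for the per-sample `attention_result`s used for interpretation.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.cellgat <- function(object, newdata,
                            type = c("prob", "class", "attention"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "point_pattern")) newdata <- list(newdata)
  outs <- lapply(newdata, cellgat_forward, params = object$params,
                 config = object$config)
  if (type == "attention") return(lapply(outs, `[[`, "attention"))
  pr <- t(vapply(outs, `[[`, numeric(2), "prob"))
  colnames(pr) <- object$classes
  if (type == "prob") pr
  else object$classes[max.col(pr, ties.method = "first")]
}

# --- checkpoints and attention export -----------------------------------

#' Save a fitted classifier as a JSON checkpoint
#'
#' The checkpoint is a single JSON document holding every named numeric
#' array plus the config manifest, so it is portable, diffable and
#' readable by any JSON-aware tool.
#'
#' @param model a fitted `cellgat`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cellgat_checkpoint <- function(model, path) {
  payload <- list(
    format = "cellgat-checkpoint-1",
    classes = model$classes,
    config = unclass(model$config),
    epochs = model$epochs, lr = model$lr, seed = model$seed,
    n_train = model$n_train, loss_trace = model$loss_trace,
    params = list(embedding = model$params$embedding,
                  gcn = model$params$gcn,
                  attn_w = model$params$attn_w,
                  ffn_W = model$params$ffn_W,
                  ffn_b = model$params$ffn_b))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a classifier from a JSON checkpoint
#' @param path checkpoint path written by [write_cellgat_checkpoint()].
#' @return A `cellgat` object.
#' @export
read_cellgat_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format) || x$format != "cellgat-checkpoint-1")
    stop("not a cellgat checkpoint: ", path)
  cfg <- cellgat_config(d = x$config$d, l = x$config$l, k = x$config$k,
                        cell_types = x$config$cell_types,
                        activation = x$config$activation, seed = x$config$seed)
  params <- structure(list(
    embedding = matrix(as.numeric(x$params$embedding), cfg$vocab, cfg$d,
                       dimnames = list(cfg$cell_types, NULL)),
    gcn = lapply(seq_len(cfg$l), function(t)
      matrix(as.numeric(x$params$gcn[t, , ]), cfg$d, cfg$d)),
    attn_w = as.numeric(x$params$attn_w),
    ffn_W = matrix(as.numeric(x$params$ffn_W), cfg$d, 2),
    ffn_b = as.numeric(x$params$ffn_b)), class = "cellgat_params")
  structure(list(params = params, config = cfg, classes = x$classes,
                 loss_trace = as.numeric(x$loss_trace), epochs = x$epochs,
                 lr = x$lr, seed = x$seed, n_train = x$n_train),
            class = "cellgat")
}

#' Tabulate per-cell attention for export
#'
#' @param pattern the `point_pattern` the attention was computed on.
#' @param att its `attention_result`.
#' @param q percentile used for the `selected` flag (default 90: the
#'   high-attention cells typically highlighted on images).
#' @return data.frame with columns `cell`, `x`, `y`, `cell_type`, `alpha`,
#'   `p`, `selected` — consumable by any plotting tool.
#' @export
attention_table <- function(pattern, att, q = 90) {
  sel <- attention_percentile_mask(att, q)
  data.frame(cell = seq_len(n_cells(pattern)),
             x = pattern$coords[, 1], y = pattern$coords[, 2],
             cell_type = as.character(pattern$labels),
             alpha = att$alpha, p = att$p,
             selected = seq_len(n_cells(pattern)) %in% sel)
}
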