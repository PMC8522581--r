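#' Quadrat counts of a multi-type point pattern
#'
#' Partitions the bounding box of all cells into a gx x gy grid of
#' half-open quadrats \[left, right) x \[bottom, top), with the max-edge
#' quadrats closed so every cell lands in exactly one bin, and counts
#' cells of each type per quadrat.
#'
#' @param pattern a `point_pattern`.
#' @param gx,gy quadrats per axis (>= 1 each; default 10 x 10).
#' @return Object of class `"quadrat_counts"`: list with `grid = c(gx, gy)`
#'   and `counts`, a (gx * gy) x V integer matrix with one column per
#'   cell type (types absent from the pattern get a zero column).
#' @export
quadrat_counts <- function(pattern, gx = 10L, gy = 10L) {
  if (gx < 1 || gy < 1) stop("grid dimensions must be >= 1")
  xy <- pattern$coords
  bx <- range(xy[, 1]); by <- range(xy[, 2])
  ix <- bin_index(xy[, 1], bx[1], bx[2], gx)
  iy <- bin_index(xy[, 2], by[1], by[2], gy)
  cell <- factor((iy - 1L) * gx + ix, levels = seq_len(gx * gy))
  counts <- sapply(pattern$cell_types, function(ct)
    as.integer(table(cell[pattern$labels == ct])))
  counts <- matrix(as.integer(counts), nrow = gx * gy,
                   dimnames = list(NULL, pattern$cell_types))
  structure(list(grid = c(gx = gx, gy = gy), counts = counts),
            class = "quadrat_counts")
}

bin_index <- function(v, lo, hi, g) {
  if (hi == lo) return(rep(1L, length(v)))       # degenerate axis: one bin
  i <- floor((v - lo) / (hi - lo) * g) + 1L
  pmin(as.integer(i), g)                          # closes the max edge
}

#' Morisita-Horn overlap between two count vectors
#'
#' The standard Morisita-Horn similarity
#' `MH = 2 * sum(x * y) / ((lambda_x + lambda_y) * X * Y)` with
#' `lambda_x = sum(x^2) / X^2`, `X = sum(x)` (and likewise for y):
#' 1 for proportionally identical distributions, 0 for disjoint supports.
#'
#' @param x,y equal-length nonnegative count vectors with positive sums.
#' @return Object of class `"mh_result"`: list with `similarity`,
#'   `dissimilarity = 1 - similarity` (both in \[0, 1\]) and `pair`
#'   (names of x/y if present).
#' @export
morisita_horn <- function(x, y) {
  if (length(x) != length(y)) stop("count vectors must have equal length")
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0)
    stop("Morisita-Horn index undefined for an all-zero count vector")
  lx <- sum(x^2) / X^2
  ly <- sum(y^2) / Y^2
  sim <- 2 * sum(x * y) / ((lx + ly) * X * Y)
  sim <- min(max(sim, 0), 1)
  structure(list(similarity = sim, dissimilarity = 1 - sim,
                 pair = c(deparse(substitute(x)), deparse(substitute(y)))),
            class = "mh_result")
}

#' @export
print.mh_result <- function(x, ...) {
  cat(sprintf("Morisita-Horn similarity %.4f (dissimilarity %.4f)\n",
              x$similarity, x$dissimilarity))
  invisible(x)
}

#' Single Morisita-Horn dissimilarity feature per image
#'
#' Computes one scalar per sample: the MH dissimilarity between the
#' quadrat-count distributions of two phenotype groups. The default
#' pairing contrasts epithelial cells with the pooled immune compartment
#' (CTL + Treg), the tumour-vs-immune contrast of interest when three
#' phenotypes must be reduced to a single index.
#'
#' @param pattern a `point_pattern`.
#' @param group_a,group_b character vectors of cell types to pool on each
#'   side.
#' @param gx,gy quadrat grid (default 10 x 10 over the image bounding box).
#' @return The MH dissimilarity in \[0, 1\], or `NA_real_` (with a
#'   warning) when either group has no cells.
#' @export
mh_feature <- function(pattern, group_a = "Epithelial",
                       group_b = c("CTL", "Treg"), gx = 10L, gy = 10L) {
  qc <- quadrat_counts(pattern, gx, gy)
  a <- rowSums(qc$counts[, intersect(group_a, colnames(qc$counts)),
                         drop = FALSE])
  b <- rowSums(qc$counts[, intersect(group_b, colnames(qc$counts)),
                         drop = FALSE])
  if (sum(a) == 0 || sum(b) == 0) {
    warning("empty phenotype group in sample '", pattern$sample_id,
            "'; MH feature is NA")
    return(NA_real_)
  }
  morisita_horn(a, b)$dissimilarity
}

#' Decision-tree baseline on the scalar MH feature
#'
#' Fits a depth-limited CART classifier (impurity splits, max depth 3) on
#' the per-sample Morisita-Horn dissimilarity — the single-number spatial
#' baseline the graph classifier is compared against.
#'
#' @param features numeric per-sample MH dissimilarities (NAs dropped with
#'   their labels).
#' @param labels per-sample class labels with exactly two levels.
#' @param seed RNG seed (CART here is deterministic, but the seed is fixed
#'   for a stable contract).
#' @param maxdepth tree depth cap.
#' @return Object of class `"mh_tree"` with `fit` (the rpart object) and
#'   `classes`; supports `predict(, type = "prob"|"class")`.
#' @export
train_mh_tree <- function(features, labels, seed = 1L, maxdepth = 3L) {
  keep <- !is.na(features)
  features <- features[keep]
  labels <- as.character(labels)[keep]
  cls <- sort(unique(labels))
  if (length(cls) != 2)
    stop("MH baseline needs exactly two classes, got ",
         paste(cls, collapse = ", "))
  df <- data.frame(mh = features, y = factor(labels, levels = cls))
  set.seed(seed)
  fit <- rpart::rpart(y ~ mh, data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = maxdepth, minsplit = 2, minbucket = 1,
                        cp = 0, xval = 0))
  structure(list(fit = fit, classes = cls), class = "mh_tree")
}

#' @export
predict.mh_tree <- function(object, newdata, type = c("prob", "class"),
                            ...) {
  type <- match.arg(type)
  if (!is.data.frame(newdata)) newdata <- data.frame(mh = newdata)
  pr <- stats::predict(object$fit, newdata, type = "prob")
  if (type == "prob") pr
  else object$classes[max.col(pr, ties.method = "first")]
}

#' @export
print.mh_tree <- function(x, ...) {
  cat("Morisita-Horn decision-tree baseline (", x$classes[1], " vs ",
      x$classes[2], ")\n", sep = "")
  print(x$fit)
  invisible(x)
}
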