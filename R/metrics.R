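#' Stratified train/test split of a labelled cohort
#'
#' Randomly assigns about `train_fraction` of each class's samples to the
#' training set (rounded per class), the rest to the test set; seeded,
#' disjoint and together exhaustive.
#'
#' @param labels per-sample class labels (character/factor), or a cohort
#'   list of `point_pattern`s (their `disease_class` is used).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, train_fraction = 0.8, seed = 1L) {
  labels <- cohort_labels(labels)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  tab <- table(labels)
  if (any(tab < 2))
    stop("every class needs >= 2 samples to split; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Stratified k-fold assignments
#'
#' Splits samples into `folds` near-equal groups, stratified by class;
#' every sample lands in exactly one fold. When a class has fewer samples
#' than folds its members are spread over distinct folds with a warning.
#'
#' @param labels per-sample class labels or a cohort list.
#' @param folds number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1:folds`, one per sample.
#' @export
kfold_indices <- function(labels, folds = 5L, seed = 1L) {
  labels <- cohort_labels(labels)
  if (folds < 2) stop("need at least 2 folds")
  tab <- table(labels)
  if (any(tab < folds))
    warning("class(es) with fewer samples than folds: ",
            paste(names(tab)[tab < folds], collapse = ", "),
            "; some folds will lack them")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample.int(folds), length(idx))
  }
  fold
}

cohort_labels <- function(x) {
  if (is.list(x) && length(x) && inherits(x[[1]], "point_pattern"))
    vapply(x, function(p) p$disease_class, character(1))
  else as.character(x)
}

#' Rank-based area under the ROC curve
#'
#' Computed from midranks (equivalent to the Mann-Whitney statistic), so
#' tied scores contribute half a concordant pair.
#'
#' @param scores numeric predicted scores for the positive class.
#' @param labels binary truth: logical, 0/1, or a factor/character with
#'   exactly two values — the larger (or `positive`) one is positive.
#' @param positive optional positive-class symbol.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (is.logical(labels)) pos <- labels
  else if (is.numeric(labels)) pos <- labels == max(labels)
  else {
    lv <- sort(unique(as.character(labels)))
    if (is.null(positive)) positive <- lv[length(lv)]
    pos <- as.character(labels) == positive
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix and support-weighted classification metrics
#'
#' Builds the C x C confusion matrix (rows = true class, columns =
#' predicted) and per-class precision (over predicted columns), recall
#' (over true rows) and F1, then support-weights them by the true-class
#' counts. Weighted recall is identically the overall accuracy. A class
#' that is never predicted has undefined precision; it contributes 0,
#' with a warning (standard zero-division convention).
#'
#' @param y_true,y_pred equal-length class label vectors.
#' @param class_order ordered class symbols; every label must belong to it.
#' @return List of class `"cellgat_metrics"` with `confusion` (integer
#'   matrix with named rows/columns), `per_class` (data.frame: class,
#'   support, precision, recall, f1), `weighted` (named numeric:
#'   precision, recall, f1) and `accuracy`.
#' @export
confusion_and_weighted_metrics <- function(y_true, y_pred,
                                           class_order = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(class_order)) class_order <- sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad))
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, class_order), factor(y_pred, class_order))
  cm <- matrix(as.integer(cm), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  metrics_from_confusion(cm)
}

#' Weighted metrics from an existing confusion matrix
#'
#' @param cm square integer matrix, rows = true class, columns =
#'   predicted, with matching row/column name order.
#' @return Same structure as [confusion_and_weighted_metrics()].
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  tp <- diag(cm)
  prec <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  if (any(pred_tot == 0 & support > 0))
    warning("class(es) never predicted get precision 0: ",
            paste(classes[pred_tot == 0 & support > 0], collapse = ", "))
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- support / sum(support)
  weighted <- c(precision = sum(wts * prec), recall = sum(wts * rec),
                f1 = sum(wts * f1))
  structure(list(
    confusion = cm,
    per_class = data.frame(class = classes, support = as.integer(support),
                           precision = prec, recall = rec, f1 = f1,
                           row.names = NULL, stringsAsFactors = FALSE),
    weighted = weighted,
    accuracy = sum(tp) / sum(cm)),
    class = "cellgat_metrics")
}

#' @export
print.cellgat_metrics <- function(x, digits = 2, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(x$confusion)
  # display rounding: 2 decimals, banker's rounding; internals keep full
  # precision
  w <- round(x$weighted, digits)
  cat(sprintf("weighted precision %.2f, recall %.2f, F1 %.2f (accuracy %.2f)\n",
              w["precision"], w["recall"], w["f1"],
              round(x$accuracy, digits)))
  invisible(x)
}

#' Cross-validated evaluation of one pairwise classifier
#'
#' Runs stratified k-fold cross-validation of [cellgat()] within a
#' training cohort: for each fold the model is fitted on the other folds
#' and scored on the held-out fold; AUC, precision and recall are
#' reported per fold and as mean +/- sample standard deviation across
#' folds.
#'
#' @param cohort list of labelled `point_pattern`s (two classes).
#' @param classes the class pair `(positive, negative)`.
#' @param folds number of folds (default 5).
#' @param config,epochs,lr passed to [cellgat()].
#' @param seed seed for the fold assignment.
#' @return List with `per_fold` (data.frame: fold, auc, precision,
#'   recall) and `summary` (data.frame: metric, mean, sd).
#' @export
crossval_pairwise <- function(cohort, classes, folds = 5L,
                              config = cellgat_config(), epochs = 100L,
                              lr = 1e-3, seed = 1L) {
  y <- cohort_labels(cohort)
  keep <- y %in% classes
  cohort <- cohort[keep]; y <- y[keep]
  fold <- kfold_indices(y, folds = folds, seed = seed)
  rows <- lapply(sort(unique(fold)), function(f) {
    tr <- cohort[fold != f]; te <- cohort[fold == f]
    if (length(unique(cohort_labels(tr))) < 2 || length(te) == 0)
      return(NULL)
    fit <- cellgat(tr, classes = classes, config = config,
                   epochs = epochs, lr = lr)
    pr <- predict(fit, te, type = "prob")
    truth <- cohort_labels(te)
    pred <- classes[max.col(pr, ties.method = "first")]
    auc <- if (length(unique(truth)) == 2)
      roc_auc(pr[, 1], truth == classes[1]) else NA_real_
    tp <- sum(pred == classes[1] & truth == classes[1])
    data.frame(fold = f, auc = auc,
               precision = if (sum(pred == classes[1]))
                 tp / sum(pred == classes[1]) else 0,
               recall = if (sum(truth == classes[1]))
                 tp / sum(truth == classes[1]) else NA_real_)
  })
  per_fold <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("auc", "precision", "recall"),
    mean = vapply(c("auc", "precision", "recall"),
                  function(m) mean(per_fold[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(c("auc", "precision", "recall"),
                function(m) stats::sd(per_fold[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  list(per_fold = per_fold, summary = summ)
}
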