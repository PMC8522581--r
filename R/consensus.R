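pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Binary vote of a pairwise model on one sample
#'
#' Generic used by the consensus predictor: given a model trained on a
#' class pair, return the single class it votes for on `pattern`. The
#' `cellgat` method votes by arg-max of the two soft-max probabilities
#' (threshold 0.5, no calibration).
#'
#' @param model a pairwise model.
#' @param pattern a `point_pattern`.
#' @return A single class symbol.
#' @export
pairwise_vote <- function(model, pattern) UseMethod("pairwise_vote")

#' @export
pairwise_vote.cellgat <- function(model, pattern) {
  pr <- predict(model, pattern, type = "prob")
  model$classes[which.max(pr[1, ])]
}

#' Deterministic stub pairwise model
#'
#' A fixed-decision stand-in for a trained pairwise classifier, used to
#' audit the consensus rule in isolation (the consensus output must be a
#' function of the 15 binary votes only).
#'
#' @param classes length-2 class pair.
#' @param decide either a single class symbol (always vote that class) or
#'   a function `f(pattern)` returning one of the two classes.
#' @return Object of class `"cellgat_stub"` usable wherever a pairwise
#'   model is expected.
#' @export
stub_pairwise_model <- function(classes, decide) {
  stopifnot(length(classes) == 2)
  if (!is.function(decide)) {
    fixed <- decide
    stopifnot(fixed %in% classes)
    decide <- function(pattern) fixed
  }
  structure(list(classes = classes, decide = decide),
            class = "cellgat_stub")
}

#' @export
pairwise_vote.cellgat_stub <- function(model, pattern) {
  v <- model$decide(pattern)
  if (!v %in% model$classes) stop("stub voted outside its class pair")
  v
}

#' Assemble a rule-based multi-class consensus classifier
#'
#' Combines the C(C, 2) pretrained pairwise classifiers of a C-class
#' problem into one predictor. No new training happens here; prediction
#' is rule-based (see [predict.cellgat_consensus()]).
#'
#' @param models list of pairwise models (each exposing a class pair via
#'   `$classes` and a [pairwise_vote()] method) covering every unordered
#'   pair of `classes` exactly once.
#' @param classes the full class set; defaults to the union of the pairs.
#' @param priority ordered class list tried first by the unanimity stage.
#'   The default puts the empirically strongest classes (PDAC, then CP)
#'   first; it must be a permutation of `classes`.
#' @return Object of class `"cellgat_consensus"`.
#' @export
cellgat_consensus <- function(models, classes = NULL, priority = NULL) {
  pairs <- lapply(models, function(m) m$classes)
  if (is.null(classes)) classes <- sort(unique(unlist(pairs)))
  keys <- vapply(pairs, function(p) pair_key(p[1], p[2]), character(1))
  if (anyDuplicated(keys))
    stop("duplicate pairwise model for pair ", keys[duplicated(keys)][1])
  want <- utils::combn(classes, 2, function(p) pair_key(p[1], p[2]))
  miss <- setdiff(want, keys)
  if (length(miss))
    stop("missing pairwise model(s): ", paste(miss, collapse = "; "))
  names(models) <- keys
  if (is.null(priority)) {
    pref <- c("PDAC", "CP", "IPMN", "IPMN-associated PDAC", "PanIN", "MCN")
    priority <- c(intersect(pref, classes), setdiff(classes, pref))
  }
  if (!setequal(priority, classes) || length(priority) != length(classes))
    stop("'priority' must be a permutation of the class set")
  structure(list(models = models, classes = classes, priority = priority),
            class = "cellgat_consensus")
}

#' @export
print.cellgat_consensus <- function(x, ...) {
  cat("Consensus classifier over", length(x$classes), "classes (",
      length(x$models), "pairwise models )\n")
  cat("priority:", paste(x$priority, collapse = " > "), "\n")
  invisible(x)
}

#' Predict with the consensus rule
#'
#' Stage 1 (unanimity): classes are tried in priority order; the first
#' class whose five pairwise classifiers all vote for it wins. Stage 2
#' (fallback round-robin): if no class is unanimous, the class with most
#' pairwise wins is returned, ties broken by priority order. The full
#' vote table is always returned for audit.
#'
#' @param object a `cellgat_consensus`.
#' @param newdata a `point_pattern` or list of them.
#' @param ... unused.
#' @return For a single pattern, a list with `class`, `stage`
#'   (`"unanimous"` or `"tournament"`), `wins` (named win counts) and
#'   `votes` (data.frame: class_a, class_b, vote). For a list, a
#'   data.frame with one row per sample (`sample_id`, `class`, `stage`).
#' @export
predict.cellgat_consensus <- function(object, newdata, ...) {
  if (!inherits(newdata, "point_pattern")) {
    rows <- lapply(newdata, function(p) {
      r <- predict(object, p)
      data.frame(sample_id = p$sample_id, class = r$class, stage = r$stage,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  votes <- data.frame(
    class_a = vapply(object$models, function(m) m$classes[1], character(1)),
    class_b = vapply(object$models, function(m) m$classes[2], character(1)),
    vote = vapply(object$models, pairwise_vote, character(1),
                  pattern = newdata),
    row.names = NULL, stringsAsFactors = FALSE)
  consensus_from_votes(votes, object$priority)
}

# Pure rule: the prediction depends on the vote table alone.
consensus_from_votes <- function(votes, priority) {
  for (cl in priority) {
    inv <- votes$class_a == cl | votes$class_b == cl
    if (sum(inv) > 0 && all(votes$vote[inv] == cl))
      return(list(class = cl, stage = "unanimous",
                  wins = win_counts(votes, priority), votes = votes))
  }
  wins <- win_counts(votes, priority)
  best <- priority[which.max(wins[priority])]   # which.max: first max wins
  list(class = best, stage = "tournament", wins = wins, votes = votes)
}

win_counts <- function(votes, classes) {
  w <- stats::setNames(integer(length(classes)), classes)
  tv <- table(votes$vote)
  w[names(tv)] <- as.integer(tv)
  w
}

#' Train all pairwise classifiers and assemble the consensus
#'
#' Convenience wrapper: fits one [cellgat()] per unordered class pair on
#' the samples of those two classes and wraps them with
#' [cellgat_consensus()].
#'
#' @param cohort list of labelled `point_pattern`s.
#' @param classes class set (default: classes present in the cohort).
#' @param config,epochs,lr passed to [cellgat()]; the per-pair seed is
#'   `config$seed` offset by the pair index so the pairwise fits are
#'   independently initialized yet reproducible.
#' @param priority passed to [cellgat_consensus()].
#' @param verbose print progress per pair.
#' @return A `cellgat_consensus`.
#' @export
fit_consensus <- function(cohort, classes = NULL, config = cellgat_config(),
                          epochs = 100L, lr = 1e-3, priority = NULL,
                          verbose = FALSE) {
  y <- vapply(cohort, function(p) p$disease_class, character(1))
  if (is.null(classes)) classes <- sort(unique(y))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    if (verbose) cat("fitting", pr[1], "vs", pr[2], "\n")
    cfg <- config
    cfg$seed <- config$seed + i
    models[[i]] <- cellgat(cohort[y %in% pr], classes = pr, config = cfg,
                           epochs = epochs, lr = lr)
  }
  cellgat_consensus(models, classes = classes, priority = priority)
}
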