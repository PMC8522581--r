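#' Specification of one synthetic disease class
#'
#' Describes a Thomas-process-style clustered multi-type pattern: per
#' type, cluster parents are scattered uniformly over a rectangular
#' window, the realized cell count is Poisson around its expectation and
#' offspring fall isotropically (Gaussian) around a parent. The `mixing`
#' coefficient in \[0, 1\] is the planted biology: it is the probability
#' that an immune cell attaches to an *epithelial* cluster parent instead
#' of one of its own type, so mixing 0 gives spatially segregated immune
#' infiltrates and mixing 1 puts every immune cell at the tumour
#' interface.
#'
#' @param counts named expected cell counts per type (>= 0).
#' @param parents named number of cluster parents per type (>= 1).
#' @param spread offspring standard deviation around the parent, in
#'   window units (> 0).
#' @param mixing interface coefficient in \[0, 1\].
#' @param window c(width, height) of the rectangular extent.
#' @param immune_types which types the mixing bias applies to.
#' @param epithelial_type the anchor type whose parents attract mixed
#'   immune cells.
#' @return List of class `"class_spec"`.
#' @export
class_spec <- function(counts = c(Epithelial = 350, CTL = 100, Treg = 60),
                       parents = c(Epithelial = 12, CTL = 6, Treg = 6),
                       spread = 35, mixing = 0.5,
                       window = c(1000, 1000),
                       immune_types = c("CTL", "Treg"),
                       epithelial_type = "Epithelial") {
  if (any(counts < 0)) stop("expected counts must be >= 0")
  if (spread <= 0) stop("cluster spread must be > 0")
  if (mixing < 0 || mixing > 1) stop("mixing must lie in [0, 1]")
  if (any(window <= 0)) stop("window must have positive extent")
  structure(list(counts = counts, parents = parents, spread = spread,
                 mixing = mixing, window = window,
                 immune_types = immune_types,
                 epithelial_type = epithelial_type),
            class = "class_spec")
}

#' Generate one synthetic multi-type point pattern
#'
#' @param spec a [class_spec()].
#' @param seed RNG seed; the same seed reproduces the pattern exactly.
#' @param sample_id,disease_class metadata for the resulting pattern.
#' @param cell_types label dictionary of the output pattern; defaults to
#'   the names of `spec$counts`.
#' @return A `point_pattern`.
#' @export
generate_pattern <- function(spec, seed = 1L, sample_id = "synthetic",
                             disease_class = NA_character_,
                             cell_types = names(spec$counts)) {
  set.seed(seed)
  w <- spec$window
  types <- names(spec$counts)
  n_type <- stats::setNames(stats::rpois(length(types), spec$counts), types)
  if (sum(n_type) == 0)                       # guarantee N >= 1
    n_type[which.max(spec$counts)] <- 1L
  parent_xy <- lapply(types, function(tt) {
    np <- max(1L, as.integer(spec$parents[tt]))
    cbind(stats::runif(np, 0, w[1]), stats::runif(np, 0, w[2]))
  })
  names(parent_xy) <- types
  epi <- spec$epithelial_type
  xs <- ys <- numeric(0); ls <- character(0)
  for (tt in types) {
    n <- n_type[[tt]]
    if (n == 0) next
    own <- parent_xy[[tt]]
    is_immune <- tt %in% spec$immune_types && epi %in% types
    use_epi <- if (is_immune) stats::runif(n) < spec$mixing
               else rep(FALSE, n)
    pool <- own
    pick <- sample.int(nrow(own), n, replace = TRUE)
    px <- pool[pick, 1]; py <- pool[pick, 2]
    if (any(use_epi)) {
      ep <- parent_xy[[epi]]
      pe <- sample.int(nrow(ep), sum(use_epi), replace = TRUE)
      px[use_epi] <- ep[pe, 1]; py[use_epi] <- ep[pe, 2]
    }
    xs <- c(xs, px + stats::rnorm(n, sd = spec$spread))
    ys <- c(ys, py + stats::rnorm(n, sd = spec$spread))
    ls <- c(ls, rep(tt, n))
  }
  point_pattern(cbind(xs, ys), ls, sample_id = sample_id,
                cell_types = cell_types, disease_class = disease_class)
}

#' Default six-class cohort preset
#'
#' Per-class generator settings emulating the qualitative spatial
#' structure of the six pancreatic cohorts — clustered epithelium with
#' class-dependent immune abundance and interface mixing — together with
#' the study's per-class sample counts (56 CP, 41 PanIN, 21 MCN, 89 IPMN,
#' 38 IPMN-associated PDAC, 143 PDAC; 388 in total).
#'
#' @return List with `class_specs` (named list of [class_spec()]) and
#'   `counts` (named integer sample counts).
#' @export
cohort_preset <- function() {
  base <- function(mixing, ctl, treg)
    class_spec(counts = c(Epithelial = 350, CTL = ctl, Treg = treg),
               mixing = mixing)
  list(
    class_specs = list(
      "CP" = base(0.50, 140, 40),
      "IPMN" = base(0.35, 100, 60),
      "MCN" = base(0.25, 80, 50),
      "PanIN" = base(0.30, 90, 55),
      "PDAC" = base(0.85, 100, 110),
      "IPMN-associated PDAC" = base(0.70, 100, 85)),
    counts = c("CP" = 56L, "PanIN" = 41L, "MCN" = 21L, "IPMN" = 89L,
               "IPMN-associated PDAC" = 38L, "PDAC" = 143L))
}

#' Generate a labelled synthetic cohort
#'
#' @param class_specs named list of [class_spec()]s, one per class.
#' @param counts named per-class sample counts (>= 1 per requested
#'   class). With the defaults (the [cohort_preset()]) this mirrors the
#'   388-sample imbalanced cohort.
#' @param seed master seed; per-sample seeds are drawn from it so cohorts
#'   with different seeds are disjoint realizations.
#' @param scale multiply every class's sample count by this factor
#'   (rounded, minimum 1 for classes with positive count; scale 0 drops a
#'   class).
#' @return List of `point_pattern`s with `disease_class` set.
#' @export
generate_cohort <- function(class_specs = cohort_preset()$class_specs,
                            counts = cohort_preset()$counts,
                            seed = 1L, scale = 1) {
  bad <- setdiff(names(counts), names(class_specs))
  if (length(bad))
    stop("no class_spec for class(es): ", paste(bad, collapse = ", "))
  n_per <- vapply(counts * scale, function(x)
    if (x <= 0) 0L else max(1L, as.integer(round(x))), integer(1))
  total <- sum(n_per)
  if (total < 1) stop("cohort would be empty")
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, total)
  out <- vector("list", total)
  i <- 0L
  for (cl in names(counts)) {
    for (j in seq_len(n_per[[cl]])) {
      i <- i + 1L
      out[[i]] <- generate_pattern(class_specs[[cl]], seed = sample_seeds[i],
                                   sample_id = sprintf("%s_%03d",
                                                       gsub("[^A-Za-z0-9]+",
                                                            "-", cl), j),
                                   disease_class = cl)
    }
  }
  out
}

#' Two-class cohorts used for method benchmarking
#'
#' Convenience generators for the two study conditions exercised in the
#' package's own evaluation: a *planted* pair whose classes differ only
#' in interface mixing (low vs high), and an *overlapping* pair whose
#' mixing coefficients coincide so that any single spatial-overlap
#' summary carries no class signal.
#'
#' @param n_per_class samples per class.
#' @param seed master seed.
#' @param mixing length-2 mixing coefficients for classes A and B.
#' @param cells expected cells per sample (split 70/20/10 over
#'   Epithelial/CTL/Treg).
#' @return List of `point_pattern`s with classes `"A"` and `"B"`.
#' @export
benchmark_cohort <- function(n_per_class = 40L, seed = 1L,
                             mixing = c(0.1, 0.9), cells = 400) {
  mk <- function(mx) class_spec(
    counts = c(Epithelial = 0.7, CTL = 0.2, Treg = 0.1) * cells,
    parents = c(Epithelial = 10, CTL = 5, Treg = 5),
    mixing = mx)
  generate_cohort(class_specs = list(A = mk(mixing[1]), B = mk(mixing[2])),
                  counts = c(A = n_per_class, B = n_per_class), seed = seed)
}
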