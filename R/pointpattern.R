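#' Default cell-type dictionary
#'
#' The three phenotypes used throughout the package unless a different
#' dictionary is supplied: pancytokeratin+ epithelial cells, CD3+CD8+
#' cytotoxic T lymphocytes (CTL) and FoxP3+ regulatory T cells (Treg).
#'
#' @return Character vector of cell-type symbols.
#' @export
default_cell_types <- function() c("Epithelial", "CTL", "Treg")

#' Default disease-class set
#'
#' The six-way pancreatic disease label set: chronic pancreatitis (CP),
#' intraductal papillary mucinous neoplasm (IPMN), mucinous cystic neoplasm
#' (MCN), pancreatic intraepithelial neoplasia (PanIN), pancreatic ductal
#' adenocarcinoma (PDAC) and IPMN-associated PDAC.
#'
#' @return Character vector of disease-class symbols.
#' @export
default_disease_classes <- function() {
  c("CP", "IPMN", "MCN", "PanIN", "PDAC", "IPMN-associated PDAC")
}

#' Construct a multi-type spatial point pattern
#'
#' A point pattern is one sample's cells: planar coordinates (arbitrary
#' units, Euclidean geometry) plus a phenotype label per cell drawn from a
#' declared label dictionary, and optionally the sample's disease class.
#'
#' @param coords numeric N x 2 matrix of cell positions (columns x, y).
#' @param labels character or factor of length N; every value must belong
#'   to `cell_types`.
#' @param sample_id single string identifying the sample.
#' @param cell_types the label dictionary (>= 2 symbols).
#' @param disease_class optional single disease-class symbol, or `NA`.
#'
#' @return An object of class `"point_pattern"` with elements `sample_id`,
#'   `coords`, `labels` (factor with levels = dictionary), `cell_types`
#'   and `disease_class`.
#' @export
point_pattern <- function(coords, labels, sample_id = "sample",
                          cell_types = default_cell_types(),
                          disease_class = NA_character_) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 2)
    stop("'coords' must be an N x 2 matrix")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  rownames(coords) <- NULL
  if (length(cell_types) < 2)
    stop("label dictionary must contain at least 2 cell types")
  labels <- as.character(labels)
  pp <- structure(
    list(sample_id = as.character(sample_id)[1],
         coords = coords,
         labels = factor(labels, levels = cell_types),
         cell_types = as.character(cell_types),
         disease_class = as.character(disease_class)[1]),
    class = "point_pattern")
  validate_point_pattern(pp)
  pp
}

validate_point_pattern <- function(pp) {
  n <- nrow(pp$coords)
  if (n < 1) stop("point pattern must contain at least one cell")
  if (!all(is.finite(pp$coords)))
    stop("coordinates must all be finite")
  if (length(pp$labels) != n)
    stop("labels length (", length(pp$labels),
         ") does not match coordinate rows (", n, ")")
  bad <- which(is.na(pp$labels))
  if (length(bad))
    stop("unknown cell-type label at row ", bad[1],
         "; dictionary is {", paste(pp$cell_types, collapse = ", "), "}")
  invisible(pp)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("Point pattern '", x$sample_id, "': ", nrow(x$coords), " cells\n",
      sep = "")
  print(table(x$labels))
  if (!is.na(x$disease_class))
    cat("disease class:", x$disease_class, "\n")
  invisible(x)
}

#' Number of cells in a point pattern
#' @param pattern a `point_pattern`.
#' @return Integer cell count N.
#' @export
n_cells <- function(pattern) nrow(pattern$coords)

#' Read a point-pattern sample from CSV
#'
#' Expects a comma-separated UTF-8 file with mandatory header and columns
#' `x`, `y`, `cell_type`. Row order is preserved; coordinates are parsed as
#' reals and kept in their input units (the graph construction only uses
#' relative Euclidean distances, so units are opaque).
#'
#' @param path path to the CSV file.
#' @param cell_types label dictionary; any label outside it is an error,
#'   never silently coerced.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param disease_class optional class symbol attached to the sample
#'   (normally supplied via the cohort manifest, not the per-sample file).
#' @return A validated [point_pattern()].
#' @export
read_point_pattern <- function(path, cell_types = default_cell_types(),
                               sample_id = NULL,
                               disease_class = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("x", "y", "cell_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed point-pattern file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0)
    stop("point-pattern file ", path, " contains no cells")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  point_pattern(cbind(as.numeric(df$x), as.numeric(df$y)), df$cell_type,
                sample_id = sample_id, cell_types = cell_types,
                disease_class = disease_class)
}

#' Write a point-pattern sample to CSV
#'
#' Writes the three-column schema `x,y,cell_type` (header mandatory, full
#' decimal precision). The disease class is deliberately not serialized
#' here; it lives in the cohort manifest.
#'
#' @param pattern a valid `point_pattern`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  validate_point_pattern(pattern)
  df <- data.frame(x = sprintf("%.17g", pattern$coords[, 1]),
                   y = sprintf("%.17g", pattern$coords[, 2]),
                   cell_type = as.character(pattern$labels),
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write point pattern to ", path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `path` and `disease_class` mapping
#' per-sample files to disease-class labels. Paths must be unique and every
#' class must belong to `class_set`.
#'
#' @param path manifest CSV path.
#' @param class_set ordered disease-class symbol list.
#' @param relative_to directory against which relative sample paths are
#'   resolved; defaults to the manifest's directory.
#' @return data.frame with columns `path` (resolved) and `disease_class`.
#' @export
read_cohort_manifest <- function(path, class_set = default_disease_classes(),
                                 relative_to = dirname(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(c("path", "disease_class"), names(df))
  if (length(miss))
    stop("malformed manifest: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$path))
    stop("manifest contains duplicate sample paths")
  bad <- setdiff(unique(df$disease_class), class_set)
  if (length(bad))
    stop("manifest contains class(es) outside the class set: ",
         paste(bad, collapse = ", "))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(relative_to, df$path))
  data.frame(path = abs, disease_class = df$disease_class,
             stringsAsFactors = FALSE)
}

#' Write a cohort manifest
#' @param df data.frame with columns `path`, `disease_class`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(df, path) {
  utils::write.csv(df[, c("path", "disease_class")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read every sample of a cohort
#'
#' @param manifest data.frame as returned by [read_cohort_manifest()].
#' @param cell_types label dictionary.
#' @return List of `point_pattern`s with `disease_class` filled in.
#' @export
read_cohort <- function(manifest, cell_types = default_cell_types()) {
  lapply(seq_len(nrow(manifest)), function(i)
    read_point_pattern(manifest$path[i], cell_types = cell_types,
                       disease_class = manifest$disease_class[i]))
}
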