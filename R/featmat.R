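#' Construct a labeled feature matrix
#'
#' The central container of the pipeline: one row per sequence sample, one
#' column per motif family, values are length-normalized hit counts (hits
#' per bp), and a per-row class label, \code{1} for nucleosome core
#' (positive) and \code{2} for linker (negative).
#'
#' @param values numeric matrix (samples x families) of non-negative,
#'   finite length-normalized counts; column names are the family names.
#' @param labels integer vector of class labels in \code{{1, 2}}.
#' @param sample_ids optional character ids (default taken from rownames).
#' @return An object of class \code{feature_matrix}: a list with elements
#'   \code{values} and \code{labels}.
#' @export
feature_matrix <- function(values, labels, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.integer(labels)
  if (nrow(values) != length(labels))
    stop("row count (", nrow(values), ") != label count (", length(labels),
         ")")
  if (length(labels) && !all(labels %in% c(1L, 2L)))
    stop("labels must be 1 (nucleosome) or 2 (linker)")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("feature values must be finite and >= 0")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("F%02d", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("family names must be unique")
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  structure(list(values = values, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix: %d samples (%d nucleosome, %d linker) x %d families\n",
    nrow(x$values), sum(x$labels == 1L), sum(x$labels == 2L),
    ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Family names of a feature matrix
#' @param x a \code{\link{feature_matrix}}.
#' @return Character vector of column (family) names.
#' @export
family_names <- function(x) colnames(x$values)

#' Build the length-normalized feature matrix from sequences
#'
#' Scans every sample with every motif family and stores
#' \code{hits / length} (hits per bp).  Column order follows the input
#' family order; labels are \code{1} for POSITIVE (core) and \code{2} for
#' NEGATIVE (linker) samples.
#'
#' @param samples a \code{\link{sequence_samples}} data frame.
#' @param families list of \code{\link{motif_family}} objects.
#' @return A \code{\link{feature_matrix}}.
#' @export
build_matrix <- function(samples, families) {
  stopifnot(inherits(samples, "sequence_samples"), length(families) > 0)
  if (!nrow(samples)) stop("no samples supplied")
  if (any(samples$length == 0L))
    stop("zero-length sample(s): ",
         paste(head(samples$id[samples$length == 0L], 5L), collapse = ", "))
  fam_names <- vapply(families, function(f) f$name, character(1))
  subjects <- lapply(samples$sequence,
                     function(s) Biostrings::DNAString(toupper(s)))
  counts <- vapply(families, function(fam)
    vapply(subjects, scan_family_hits, numeric(1), family = fam),
    numeric(nrow(samples)))
  counts <- matrix(counts, nrow = nrow(samples),
                   dimnames = list(samples$id, fam_names))
  feature_matrix(counts / samples$length,
                 ifelse(samples$label == "POSITIVE", 1L, 2L))
}

#' Read a labeled feature matrix file
#'
#' The file format is tab-separated: first column the class label (1 =
#' nucleosome, 2 = linker), remaining columns the length-normalized family
#' frequencies.  An optional first header line carrying the family names
#' (with or without a leading label-column name) is accepted.
#'
#' @param path path to the matrix file.
#' @return A \code{\link{feature_matrix}}.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("parse error: empty matrix file: ", path)
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  has_header <- is.na(suppressWarnings(as.numeric(first[1L])))
  fam <- NULL
  if (has_header) {
    fam <- first
    lines <- lines[-1L]
    if (!length(lines)) stop("parse error: matrix file has no data rows")
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(cells)
  if (any(nfield != nfield[1L])) {
    bad <- which(nfield != nfield[1L])[1L]
    stop("parse error: line ", bad + has_header, " has ", nfield[bad],
         " fields, expected ", nfield[1L])
  }
  if (nfield[1L] < 2L)
    stop("parse error: need a label column plus >= 1 feature column")
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))),
              nrow = nfield[1L])
  if (anyNA(m)) {
    bad_line <- which(colSums(is.na(m)) > 0)[1L]
    stop("parse error: non-numeric cell at line ", bad_line + has_header)
  }
  labels <- m[1L, ]
  if (!all(labels %in% c(1, 2))) {
    bad_line <- which(!(labels %in% c(1, 2)))[1L]
    stop("label error: label not in {1,2} at line ", bad_line + has_header)
  }
  values <- t(m[-1L, , drop = FALSE])
  if (!is.null(fam)) {
    if (length(fam) == ncol(values) + 1L) fam <- fam[-1L]
    if (length(fam) != ncol(values))
      stop("parse error: header has ", length(fam),
           " names for ", ncol(values), " feature columns")
    colnames(values) <- fam
  }
  feature_matrix(values, as.integer(labels))
}

#' Write a labeled feature matrix file
#'
#' Inverse of \code{\link{read_matrix}}; values are written with 15
#' significant digits so a round trip reproduces them to well beyond 12
#' significant digits.
#'
#' @param x a \code{\link{feature_matrix}}.
#' @param path output path.
#' @param header write a first line with the family names? (default TRUE)
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(x, path, header = TRUE) {
  stopifnot(inherits(x, "feature_matrix"))
  vals <- format(x$values, digits = 15, trim = TRUE, scientific = FALSE)
  body <- do.call(paste, c(list(x$labels), split(vals, col(vals)),
                           sep = "\t"))
  if (header) body <- c(paste(c("label", colnames(x$values)),
                              collapse = "\t"), body)
  writeLines(body, path)
  invisible(path)
}

#' Restrict a feature matrix to a subset of families
#'
#' @param x a \code{\link{feature_matrix}}.
#' @param features character vector of family names (or integer indices).
#' @return A \code{\link{feature_matrix}} with the selected columns, in
#'   the requested order.
#' @export
select_features <- function(x, features) {
  stopifnot(inherits(x, "feature_matrix"))
  if (is.character(features)) {
    missing <- setdiff(features, colnames(x$values))
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  feature_matrix(x$values[, features, drop = FALSE], x$labels)
}
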