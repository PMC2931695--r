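#' Incremental feature selection over an mRMR-ranked list
#'
#' For a ranking of N features, evaluates the N nested prefixes S_1 c S_2
#' c ... c S_N (S_i = first i ranked features) with jackknifed
#' nearest-neighbor classification, and selects the prefix with the
#' highest overall accuracy (ties go to the smallest prefix).
#'
#' @param x a \code{\link{feature_matrix}}.
#' @param ranking an \code{\link{mrmr_rank}} result (or a character vector
#'   of feature names in rank order) covering exactly the matrix features.
#' @param block_size passed to \code{\link{jackknife}}.
#' @param verbose print one progress line per prefix.
#' @return An object of class \code{ifs_curve}: list with
#'   \item{records}{data frame \code{size, acc_pos, acc_neg, acc_overall};}
#'   \item{optimal_size}{the vertex prefix size h;}
#'   \item{optimal_features}{character vector S_h;}
#'   \item{order}{the full ranked feature order;}
#'   \item{reports}{per-prefix \code{accuracy_report}s.}
#' @export
ifs_curve <- function(x, ranking, block_size = 2048L, verbose = FALSE) {
  stopifnot(inherits(x, "feature_matrix"))
  ord <- if (inherits(ranking, "mrmr_ranking")) ranking$order
         else as.character(ranking)
  if (!setequal(ord, colnames(x$values)) ||
      length(ord) != ncol(x$values))
    stop("ranking features do not match the matrix features")
  n <- length(ord)
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    reports[[i]] <- jackknife(x, features = ord[seq_len(i)],
                              block_size = block_size)
    if (verbose)
      message(sprintf("IFS prefix %d/%d: overall %.4f", i, n,
                      reports[[i]]$acc_overall))
  }
  rec <- data.frame(
    size = seq_len(n),
    acc_pos = vapply(reports, `[[`, numeric(1), "acc_pos"),
    acc_neg = vapply(reports, `[[`, numeric(1), "acc_neg"),
    acc_overall = vapply(reports, `[[`, numeric(1), "acc_overall"))
  h <- which.max(rec$acc_overall)    # first max = smallest prefix
  structure(list(records = rec, optimal_size = h,
                 optimal_features = ord[seq_len(h)], order = ord,
                 reports = reports),
            class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf(
    "IFS curve over %d prefixes; vertex at %d features (overall %.4f)\n",
    nrow(x$records), x$optimal_size,
    x$records$acc_overall[x$optimal_size]))
  invisible(x)
}

#' Write the IFS curve as a TSV table
#'
#' One row per prefix size with the three jackknife accuracy rates.
#'
#' @param curve an \code{\link{ifs_curve}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ifs <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  write.table(curve$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Plot the IFS curve with its vertex annotated
#'
#' @param curve an \code{\link{ifs_curve}} result.
#' @param path optional output image path (\code{.png} or \code{.pdf});
#'   if \code{NULL}, draws on the current device.
#' @param ... further arguments passed to \code{plot}.
#' @return \code{path} (or \code{NULL}), invisibly.
#' @export
plot_curve <- function(curve, path = NULL, ...) {
  stopifnot(inherits(curve, "ifs_curve"), nrow(curve$records) > 0)
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           png = grDevices::png(path, width = 900, height = 600),
           pdf = grDevices::pdf(path, width = 9, height = 6),
           stop("unsupported plot format: ", ext))
    on.exit(grDevices::dev.off())
  }
  rec <- curve$records
  h <- curve$optimal_size
  plot(rec$size, rec$acc_overall, type = "o", pch = 16, cex = 0.6,
       xlab = "number of top-ranked features",
       ylab = "jackknife overall accuracy", ...)
  points(h, rec$acc_overall[h], pch = 19, col = "red", cex = 1.2)
  text(h, rec$acc_overall[h],
       sprintf("vertex: %.2f%% with %d features",
               100 * rec$acc_overall[h], h),
       pos = if (h > nrow(rec) / 2) 2 else 4, col = "red")
  invisible(path)
}
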