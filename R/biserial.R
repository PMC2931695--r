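#' Point-biserial correlation between a feature and the class label
#'
#' \code{r_pb = (M1 - M0) / s_n * sqrt(p * q)}, where M1 and M0 are the
#' feature means in the positive (nucleosome, label 1) and negative
#' (linker, label 2) classes, s_n is the population (divisor n) standard
#' deviation over all samples, and p, q are the class sample proportions.
#' With this convention r_pb equals the Pearson correlation between the
#' feature and 0/1-coded labels (nucleosome = 1), so nucleosome-enriched
#' features get r_pb > 0.
#'
#' @param values numeric feature vector.
#' @param labels integer labels, 1 = nucleosome (positive), 2 = linker
#'   (negative).
#' @return The coefficient, in [-1, 1].  A constant feature (zero overall
#'   standard deviation) is an error, not a silent 0.
#' @examples
#' point_biserial(c(3, 1, 2, 0), c(1, 1, 2, 2))  # 1/sqrt(5)
#' @export
point_biserial <- function(values, labels) {
  labels <- as.integer(labels)
  if (length(values) != length(labels))
    stop("values and labels must have equal length")
  if (!all(labels %in% c(1L, 2L))) stop("labels must be 1 or 2")
  pos <- labels == 1L
  n <- length(values)
  n1 <- sum(pos); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  s_n <- sqrt(mean((values - mean(values))^2))
  if (s_n == 0)
    stop("constant feature: point-biserial correlation is undefined")
  (mean(values[pos]) - mean(values[!pos])) / s_n *
    sqrt((n1 / n) * (n0 / n))
}

#' t-test for a point-biserial coefficient
#'
#' \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)} on n - 2 degrees of
#' freedom; the p-value is two-tailed.  \code{|r| = 1} is reported as
#' \code{t = +/-Inf, p = 0}.
#'
#' @param r_pb the coefficient.
#' @param n total sample count (>= 3).
#' @return List with \code{t_stat} and \code{p_value}.
#' @examples
#' biserial_test(0.5, 27)$t_stat  # 2.8868
#' @export
biserial_test <- function(r_pb, n) {
  if (n < 3L) stop("t-test needs n >= 3")
  if (abs(r_pb) > 1) stop("|r_pb| must be <= 1")
  if (abs(r_pb) == 1)
    return(list(t_stat = sign(r_pb) * Inf, p_value = 0))
  t_stat <- r_pb * sqrt(n - 2) / sqrt(1 - r_pb^2)
  list(t_stat = t_stat, p_value = 2 * pt(-abs(t_stat), df = n - 2))
}

#' Classify features as nucleosome-forming or nucleosome-inhibiting
#'
#' For each selected family, computes the point-biserial correlation with
#' the core/linker label and its t-test.  A family is called FORMING when
#' r_pb > 0 with p < alpha (enriched in nucleosome cores), INHIBITING
#' when r_pb < 0 with p < alpha (enriched in linkers), and
#' NOT_SIGNIFICANT otherwise.
#'
#' @param x a \code{\link{feature_matrix}}.
#' @param features families to test (names or indices); default all.
#' @param alpha significance threshold (default 0.05).
#' @return Data frame of class \code{biserial_table}, sorted by
#'   decreasing r_pb, with columns \code{feature, r_pb, M1, M0, t_stat,
#'   p_value, call} and attribute \code{n} (samples used).
#' @export
classify_features <- function(x, features = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "feature_matrix"))
  sub <- if (is.null(features)) x else select_features(x, features)
  n <- nrow(sub$values)
  pos <- sub$labels == 1L
  res <- lapply(colnames(sub$values), function(f) {
    v <- sub$values[, f]
    r <- point_biserial(v, sub$labels)
    tt <- biserial_test(r, n)
    data.frame(feature = f, r_pb = r,
               M1 = mean(v[pos]), M0 = mean(v[!pos]),
               t_stat = tt$t_stat, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$call <- ifelse(out$p_value >= alpha, "NOT_SIGNIFICANT",
                     ifelse(out$r_pb > 0, "FORMING", "INHIBITING"))
  out <- out[order(-out$r_pb), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n = n, alpha = alpha,
            class = c("biserial_table", "data.frame"))
}

#' Write a biserial feature table as TSV
#'
#' @param x a \code{\link{classify_features}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_biserial <- function(x, path) {
  stopifnot(inherits(x, "biserial_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
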