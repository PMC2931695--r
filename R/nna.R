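#' Cosine distance between two feature vectors
#'
#' \code{D(x, y) = 1 - <x, y> / (||x|| * ||y||)}; smaller means more
#' similar.  For non-negative vectors D lies in [0, 1].  The formula is
#' undefined for zero-norm vectors (short linkers can have all-zero
#' feature rows), so the package fixes the convention
#' \code{D(0, y) = 1} for \code{y != 0} and \code{D(0, 0) = 0}, which
#' keeps leave-one-out evaluation total and deterministic.
#'
#' @param x,y numeric vectors of equal length.
#' @return The distance, a scalar.
#' @examples
#' cosine_distance(c(1, 1), c(1, 0))  # 1 - sqrt(2)/2
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length (", length(x), " vs ", length(y),
         ")")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 && ny == 0) return(0)
  if (nx == 0 || ny == 0) return(1)
  1 - sum(x * y) / (nx * ny)
}

#' Classify a query vector by its nearest training neighbor
#'
#' Returns the label of the training sample with the smallest cosine
#' distance to the query, computed over the selected feature columns.
#' Distance ties are broken by the smallest training-sample index.
#'
#' @param train a \code{\link{feature_matrix}} of training samples.
#' @param query numeric vector with one value per selected feature.
#' @param features columns to use (names or indices); default all.
#' @return The predicted label, \code{1} or \code{2}.
#' @export
nn_predict <- function(train, query, features = NULL) {
  stopifnot(inherits(train, "feature_matrix"))
  if (!is.null(features) && length(features) == 0L)
    stop("empty feature subset")
  X <- if (is.null(features)) train$values else
    select_features(train, features)$values
  if (!nrow(X)) stop("empty training set")
  if (length(query) != ncol(X))
    stop("query has ", length(query), " values for ", ncol(X), " features")
  d <- canonicalize_distance(vapply(seq_len(nrow(X)), function(i)
    cosine_distance(X[i, ], query), numeric(1)))
  train$labels[which.min(d)]
}

# Distances are canonicalized to 12 decimals before any nearest-neighbor
# comparison: blocked BLAS products and a scalar double loop can disagree
# in the last ulp on mathematically equal distances (e.g. duplicated or
# proportional count rows), which would make first-index tie-breaking
# depend on summation order.  12 decimals is far below any meaningful
# distance difference and far above double rounding noise.
canonicalize_distance <- function(d) round(d, 12L)

# leave-one-out nearest-neighbor indices under cosine distance, computed
# in row blocks so ~1e5-sample matrices stay within memory; decisions are
# per-row argmin with first-index tie-breaking, as in the double-loop form
loo_nn_index <- function(X, block_size = 2048L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  nrm <- sqrt(sq)
  zero <- nrm == 0
  nn <- integer(n)
  for (lo in seq(1L, n, by = block_size)) {
    hi <- min(lo + block_size - 1L, n)
    idx <- lo:hi
    S <- X[idx, , drop = FALSE] %*% t(X)
    D <- 1 - S / (nrm[idx] %o% nrm)
    if (any(zero)) {
      bz <- zero[idx]
      if (any(bz)) {         # zero-norm query: 1 vs non-zero, 0 vs zero
        D[bz, ] <- 1
        D[bz, zero] <- 0
      }
      if (any(!bz)) D[!bz, zero] <- 1   # replaces 0/0 NaN columns
    }
    D <- canonicalize_distance(D)
    D[cbind(seq_along(idx), idx)] <- Inf     # exclude self
    nn[idx] <- max.col(-D, ties.method = "first")
  }
  nn
}

#' Jackknife (leave-one-out) evaluation of the nearest-neighbor classifier
#'
#' Each sample is singled out in turn as the test sample and classified by
#' its nearest neighbor (cosine distance, restricted to the selected
#' features) among all remaining samples.  The procedure is deterministic.
#'
#' @param x a \code{\link{feature_matrix}} with >= 2 samples.
#' @param features feature subset (names or indices); default all columns.
#' @param block_size rows per block for the blocked distance computation.
#' @return An \code{accuracy_report}: list with counts \code{n_pos},
#'   \code{n_neg}, \code{correct_pos}, \code{correct_neg}, the rates
#'   \code{acc_pos}, \code{acc_neg}, \code{acc_overall}, and the
#'   per-sample \code{predictions} (labels 1/2).
#' @examples
#' fm <- feature_matrix(rbind(c(1, 0), c(1, 0.1), c(0, 1), c(0.1, 1)),
#'                      c(1, 1, 2, 2))
#' jackknife(fm)$acc_overall  # 1
#' @export
jackknife <- function(x, features = NULL, block_size = 2048L) {
  stopifnot(inherits(x, "feature_matrix"))
  if (!is.null(features) && length(features) == 0L)
    stop("empty feature subset")
  X <- if (is.null(features)) x$values else select_features(x, features)$values
  n <- nrow(X)
  if (n < 2L) stop("jackknife needs >= 2 samples")
  if (length(unique(x$labels)) < 2L)
    stop("both classes must be present")
  nn <- loo_nn_index(X, block_size = block_size)
  pred <- x$labels[nn]
  pos <- x$labels == 1L
  rep <- list(n_pos = sum(pos), n_neg = sum(!pos),
              correct_pos = sum(pred[pos] == 1L),
              correct_neg = sum(pred[!pos] == 2L),
              predictions = pred)
  rep$acc_pos <- rep$correct_pos / rep$n_pos
  rep$acc_neg <- rep$correct_neg / rep$n_neg
  rep$acc_overall <- (rep$correct_pos + rep$correct_neg) / n
  structure(rep, class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "jackknife NNA: overall %.4f (pos %.4f on %d, neg %.4f on %d)\n",
    x$acc_overall, x$acc_pos, x$n_pos, x$acc_neg, x$n_neg))
  invisible(x)
}
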