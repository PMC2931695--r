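#' Three-state discretization at mean +/- t * sd
#'
#' Continuous feature values are mapped to three states for the
#' mutual-information computations: \code{LOW} below \code{mean - t*sd},
#' \code{HIGH} above \code{mean + t*sd}, and \code{MID} inside the closed
#' interval (boundary values are MID).  A zero-variance feature maps
#' entirely to MID.
#'
#' @param values numeric vector (one feature over all samples, >= 2 of
#'   them).
#' @param t threshold multiplier (default 1).
#' @param sd_type \code{"sample"} (divisor n-1, default) or
#'   \code{"population"} (divisor n).
#' @return Factor with levels \code{LOW, MID, HIGH}.
#' @examples
#' discretize(c(0, 0, 0, 10))  # MID MID MID HIGH
#' @export
discretize <- function(values, t = 1, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!length(values)) stop("cannot discretize an empty feature")
  if (length(values) < 2L) stop("discretization needs >= 2 samples")
  m <- mean(values)
  s <- sd(values)
  if (sd_type == "population")
    s <- s * sqrt((length(values) - 1) / length(values))
  if (is.na(s) || s == 0) {
    state <- rep(2L, length(values))
  } else {
    state <- 1L + (values >= m - t * s) + (values > m + t * s)
  }
  factor(c("LOW", "MID", "HIGH")[state], levels = c("LOW", "MID", "HIGH"))
}

#' Mutual information between two discrete variables
#'
#' Plug-in estimate from the empirical joint distribution, with the
#' convention \code{0 * log(0) = 0}.
#'
#' @param x,y equal-length vectors of discrete states (factor, integer or
#'   character).
#' @param base logarithm base; 2 (default) gives bits.
#' @return Non-negative mutual information.
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y))
    stop("x and y must have equal length (", length(x), " vs ", length(y),
         ")")
  if (!length(x)) stop("mutual information of empty vectors is undefined")
  tab <- table(x, y)
  mi_from_table(tab, base = base)
}

# MI of a contingency table; shared by mutual_information and mrmr_rank
mi_from_table <- function(tab, base = 2) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz], base = base))
}

#' Rank features by minimum-redundancy maximum-relevance
#'
#' Features are discretized once (three states at mean +/- t*sd); the
#' class label (1/2) is used as-is.  Relevance of feature f is the mutual
#' information I(f; class).  Selection is greedy under the MID
#' (difference) criterion: the first pick maximizes relevance; each later
#' pick maximizes \code{I(f; class) - mean(I(f; f_s))} over the already
#' selected features f_s.  Ties are broken by original column order.  The
#' MaxRel list (features sorted by relevance alone) is also returned.
#'
#' @param x a \code{\link{feature_matrix}} with both classes present.
#' @param t discretization threshold multiplier (default 1).
#' @param sd_type passed to \code{\link{discretize}}.
#' @return An object of class \code{mrmr_ranking}: list with
#'   \item{mrmr}{data frame \code{rank, feature, score} — the mRMR list;}
#'   \item{maxrel}{data frame \code{rank, feature, relevance} — features
#'     by decreasing relevance;}
#'   \item{order}{character vector, the mRMR-ordered feature names;}
#'   \item{relevance}{named vector of I(f; class) in input column order.}
#' @export
mrmr_rank <- function(x, t = 1, sd_type = "sample") {
  stopifnot(inherits(x, "feature_matrix"))
  nf <- ncol(x$values)
  if (nf < 1L) stop("need >= 1 feature")
  if (length(unique(x$labels)) < 2L)
    stop("both classes must be present to rank features")
  disc <- lapply(seq_len(nf), function(j)
    as.integer(discretize(x$values[, j], t = t, sd_type = sd_type)))
  y <- x$labels
  fam <- colnames(x$values)
  relevance <- vapply(disc, function(d)
    mi_from_table(table(factor(d, levels = 1:3), y)), numeric(1))
  names(relevance) <- fam

  selected <- integer(0)
  score_at_pick <- numeric(0)
  redsum <- numeric(nf)          # sum of MI with already-selected features
  candidates <- seq_len(nf)
  while (length(candidates)) {
    m <- length(selected)
    score <- if (m == 0L) relevance[candidates] else
      relevance[candidates] - redsum[candidates] / m
    pick <- candidates[which.max(score)]   # first max = smallest col index
    score_at_pick <- c(score_at_pick, score[which.max(score)])
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
    if (length(candidates)) {
      dp <- factor(disc[[pick]], levels = 1:3)
      for (j in candidates)
        redsum[j] <- redsum[j] +
          mi_from_table(table(dp, factor(disc[[j]], levels = 1:3)))
    }
  }
  maxrel_ord <- order(-relevance, seq_len(nf))
  structure(list(
    mrmr = data.frame(rank = seq_len(nf), feature = fam[selected],
                      score = unname(score_at_pick),
                      stringsAsFactors = FALSE),
    maxrel = data.frame(rank = seq_len(nf), feature = fam[maxrel_ord],
                        relevance = unname(relevance[maxrel_ord]),
                        stringsAsFactors = FALSE),
    order = fam[selected],
    relevance = relevance,
    t = t), class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat("mRMR ranking of", length(x$order), "features (MID criterion, t =",
      x$t, ")\n")
  print(head(x$mrmr, 10L))
  if (length(x$order) > 10L) cat("...\n")
  invisible(x)
}

#' Write the mRMR and MaxRel lists as TSV tables
#'
#' @param ranking an \code{\link{mrmr_rank}} result.
#' @param prefix output path prefix; writes \code{<prefix>mrmr_list.tsv}
#'   and \code{<prefix>maxrel_list.tsv} with scores rounded to 6 decimals.
#' @return The two paths, invisibly.
#' @export
write_ranking <- function(ranking, prefix) {
  stopifnot(inherits(ranking, "mrmr_ranking"))
  p1 <- paste0(prefix, "mrmr_list.tsv")
  p2 <- paste0(prefix, "maxrel_list.tsv")
  m <- ranking$mrmr; m$score <- round(m$score, 6)
  r <- ranking$maxrel; r$relevance <- round(r$relevance, 6)
  write.table(m, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(r, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
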