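#' Define a motif family
#'
#' A motif family groups binding-site patterns that are bound by related
#' transcription factors (the analogue of a matrix family such as
#' \code{F$GATA}).  Members are IUPAC consensus strings
#' (e.g. \code{"WGATAR"}) or position weight matrices: a 4-row numeric
#' matrix with rownames \code{A,C,G,T}, matched with
#' \code{Biostrings::matchPWM} at \code{pwm_min_score}.
#'
#' @param name family identifier, e.g. \code{"F$GATA"}.
#' @param members non-empty list (or character vector) of IUPAC consensus
#'   strings and/or 4-row PWM matrices.
#' @param pwm_min_score minimum PWM match score, passed to
#'   \code{Biostrings::matchPWM} (default \code{"85\%"}).
#' @return An object of class \code{motif_family}.
#' @examples
#' motif_family("F$GATA", c("WGATAR", "GATA"))
#' @export
motif_family <- function(name, members, pwm_min_score = "85%") {
  if (is.character(members)) members <- as.list(members)
  if (!length(members)) stop("motif family '", name, "' has no members")
  ok <- vapply(members, function(m) {
    (is.character(m) && length(m) == 1L && nzchar(m) &&
       !grepl("[^ACGTRYSWKMBDHVN]", m)) ||
      (is.matrix(m) && nrow(m) == 4L)
  }, logical(1))
  if (!all(ok))
    stop("members must be IUPAC consensus strings or 4-row PWMs (family '",
         name, "')")
  structure(list(name = name, members = members,
                 pwm_min_score = pwm_min_score),
            class = "motif_family")
}

#' @export
print.motif_family <- function(x, ...) {
  kind <- vapply(x$members, function(m)
    if (is.matrix(m)) "PWM" else m, character(1))
  cat(sprintf("motif_family %s: %d member(s): %s\n", x$name,
              length(x$members), paste(kind, collapse = ", ")))
  invisible(x)
}

#' Read motif-family definitions from a TSV file
#'
#' Expected columns (header required): \code{family}, \code{member_id},
#' \code{pattern}, where \code{pattern} is an IUPAC consensus string.
#' Rows sharing a \code{family} value are collected into one
#' \code{\link{motif_family}}.  PWM members are not representable in this
#' flat format; supply them programmatically.
#'
#' @param path path to the definitions file.
#' @return Named list of \code{\link{motif_family}} objects, in order of
#'   first appearance.
#' @export
read_motif_families <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
  need <- c("family", "member_id", "pattern")
  if (!all(need %in% names(tab)))
    stop("motif file must have columns: ", paste(need, collapse = ", "))
  fams <- unique(tab$family)
  out <- lapply(fams, function(f)
    motif_family(f, tab$pattern[tab$family == f]))
  names(out) <- fams
  out
}

# 5'-start positions of hits of one member pattern, per strand, on a
# DNAString subject.  Reverse-strand hits are located by matching the
# reverse complement of the pattern on the forward sequence; their 5'
# position on the reverse strand is the forward-coordinate end of the
# matched range.
member_hit_positions <- function(subject, member, pwm_min_score) {
  if (is.matrix(member)) {
    if (ncol(member) > length(subject))
      return(list(fwd = integer(), rev = integer()))
    f <- Biostrings::matchPWM(member, subject, min.score = pwm_min_score)
    r <- Biostrings::matchPWM(Biostrings::reverseComplement(member),
                              subject, min.score = pwm_min_score)
    list(fwd = BiocGenerics::start(f), rev = BiocGenerics::end(r),
         w = ncol(member))
  } else {
    if (nchar(member) > length(subject))
      return(list(fwd = integer(), rev = integer()))
    rcm <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(member)))
    f <- Biostrings::matchPattern(member, subject, fixed = "subject")
    r <- Biostrings::matchPattern(rcm, subject, fixed = "subject")
    list(fwd = BiocGenerics::start(f), rev = BiocGenerics::end(r),
         w = nchar(member))
  }
}

#' Count motif-family hits in a sequence (both strands)
#'
#' Counts the positions at which any member of the family matches,
#' scanning both strands with overlapping matches allowed.  A position
#' hit by two or more members on the same strand counts once; a
#' palindromic site matching on both strands counts twice (once per
#' strand).  Positions are identified by the 5' end of the match on its
#' strand.  \code{N} bases in the sequence never match any pattern
#' position.
#'
#' @param sequence a DNA string (character or \code{Biostrings::DNAString}).
#' @param family a \code{\link{motif_family}}.
#' @return Non-negative integer hit count.
#' @examples
#' scan_family_hits("ACGTACGT", motif_family("F$TOY", "ACGT"))  # 4
#' @export
scan_family_hits <- function(sequence, family) {
  stopifnot(inherits(family, "motif_family"))
  if (is.character(sequence)) {
    if (!nzchar(sequence)) stop("sequence must be non-empty")
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  n_pos <- Biostrings::matchPattern("N", sequence, fixed = TRUE)
  n_start <- BiocGenerics::start(n_pos)
  fwd <- integer(); rev <- integer()
  for (m in family$members) {
    h <- member_hit_positions(sequence, m, family$pwm_min_score)
    if (length(n_start) && (length(h$fwd) || length(h$rev))) {
      # drop hits whose matched range covers an N (only the pattern letter
      # N can ever match a subject N under fixed = "subject")
      covers_n <- function(range_start)
        vapply(range_start, function(s)
          any(n_start >= s & n_start <= s + h$w - 1L), logical(1))
      if (length(h$fwd)) h$fwd <- h$fwd[!covers_n(h$fwd)]
      if (length(h$rev)) h$rev <- h$rev[!covers_n(h$rev - h$w + 1L)]
    }
    fwd <- c(fwd, h$fwd)
    rev <- c(rev, h$rev)
  }
  length(unique(fwd)) + length(unique(rev))
}
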