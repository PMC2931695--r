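#' Genomic interval sets for nucleosome cores and linkers
#'
#' An \code{interval_set} is a data frame with columns \code{chrom},
#' \code{start}, \code{end} (1-based, both inclusive) plus a \code{role}
#' attribute (\code{"CORE"} or \code{"LINKER"}).  Rows are kept sorted by
#' \code{(chrom, start)}; this ordering is the contract that
#' \code{\link{derive_linkers}} relies on.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 1-based inclusive positions.
#' @param role either \code{"CORE"} or \code{"LINKER"}.
#' @return A data frame of class \code{interval_set}, sorted by
#'   \code{(chrom, start)}, with a \code{length} column (\code{end - start
#'   + 1}).
#' @examples
#' interval_set(c("chrI", "chrI"), c(100, 1), c(246, 147), role = "CORE")
#' @export
interval_set <- function(chrom, start, end, role = c("CORE", "LINKER")) {
  role <- match.arg(role)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && any(start < 1L))
    stop("interval start positions must be >= 1 (1-based coordinates)")
  if (length(start) && any(end < start))
    stop("interval end < start for row(s): ",
         paste(which(end < start), collapse = ", "))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$length <- df$end - df$start + 1L
  structure(df, role = role, class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d %s interval(s) on %d chromosome(s)\n",
              nrow(x), attr(x, "role"), length(unique(x$chrom))))
  if (nrow(x)) print(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

interval_role <- function(x) attr(x, "role")

#' Load nucleosome-core coordinates from a delimited table
#'
#' Reads a coordinate table (tab- or comma-separated, delimiter
#' auto-detected) with at least three columns giving chromosome, start and
#' end of each 147-bp nucleosome core particle site.  Columns are matched
#' by header name (\code{chrom}/\code{chr}/\code{chromosome},
#' \code{start}, \code{end}, case-insensitive) when a header is present,
#' otherwise the first three columns are taken positionally.
#'
#' @param path path to the coordinate table.
#' @param role role to assign to the loaded intervals, default
#'   \code{"CORE"}.
#' @return An \code{\link{interval_set}} sorted by \code{(chrom, start)}.
#'   Malformed rows (non-numeric positions, \code{end < start}) abort with
#'   an error naming the offending row numbers.
#' @export
load_core_sites <- function(path, role = "CORE") {
  if (!file.exists(path)) stop("coordinate table not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) return(interval_set(character(), integer(), integer(),
                                          role = role))
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  fields1 <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- length(fields1) >= 3L &&
    is.na(suppressWarnings(as.numeric(fields1[2L])))
  tab <- read.table(path, sep = sep, header = has_header,
                    stringsAsFactors = FALSE, comment.char = "",
                    colClasses = "character")
  if (ncol(tab) < 3L)
    stop("coordinate table needs >= 3 columns (chrom, start, end), found ",
         ncol(tab))
  if (has_header) {
    nm <- tolower(names(tab))
    ic <- match(TRUE, nm %in% c("chrom", "chr", "chromosome", "seqname"))
    is <- match(TRUE, nm == "start")
    ie <- match(TRUE, nm == "end")
    if (any(is.na(c(ic, is, ie)))) { ic <- 1L; is <- 2L; ie <- 3L }
  } else { ic <- 1L; is <- 2L; ie <- 3L }
  chrom <- tab[[ic]]
  start <- suppressWarnings(as.numeric(tab[[is]]))
  end <- suppressWarnings(as.numeric(tab[[ie]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("non-numeric start/end in row(s): ",
         paste(head(bad, 10L), collapse = ", "))
  bad <- which(end < start)
  if (length(bad))
    stop("end < start in row(s): ", paste(head(bad, 10L), collapse = ", "))
  interval_set(chrom, start, end, role = role)
}

#' Derive linker intervals as gaps between successive nucleosome cores
#'
#' On each chromosome, the region between every pair of successive core
#' particles is a candidate linker \code{(prev_end + 1, next_start - 1)}.
#' Gaps shorter than \code{min_len} (overlapping or book-ended cores give
#' non-positive gaps) are dropped, as are gaps longer than \code{max_len}
#' when a cap is set.  Terminal segments before the first and after the
#' last core of a chromosome are never emitted: they are not flanked by
#' nucleosomes on both sides.
#'
#' @param cores a CORE \code{\link{interval_set}}.
#' @param min_len minimum linker length in bp (default 6).
#' @param max_len optional maximum linker length in bp (default \code{NULL},
#'   no cap).
#' @return A LINKER \code{\link{interval_set}}.
#' @examples
#' cores <- interval_set("chrI", c(1, 160), c(147, 306), role = "CORE")
#' derive_linkers(cores)  # one 12-bp linker at 148..159
#' @export
derive_linkers <- function(cores, min_len = 6L, max_len = NULL) {
  if (!inherits(cores, "interval_set") || interval_role(cores) != "CORE")
    stop("'cores' must be an interval_set with role CORE")
  if (nrow(cores) && is.unsorted(order(cores$chrom, cores$start)))
    stop("internal error: core intervals are not sorted")   # load's contract
  if (nrow(cores) < 2L)
    return(interval_set(character(), integer(), integer(), role = "LINKER"))
  same_chrom <- cores$chrom[-1L] == cores$chrom[-nrow(cores)]
  lstart <- cores$end[-nrow(cores)] + 1L
  lend <- cores$start[-1L] - 1L
  lchrom <- cores$chrom[-1L]
  len <- lend - lstart + 1L
  keep <- same_chrom & len >= min_len
  if (!is.null(max_len)) keep <- keep & len <= max_len
  interval_set(lchrom[keep], lstart[keep], lend[keep], role = "LINKER")
}

#' Write an interval set as TSV (1-based) or BED (0-based half-open)
#'
#' @param x an \code{\link{interval_set}}.
#' @param path output file path.
#' @param format \code{"tsv"} keeps the internal 1-based inclusive
#'   coordinates; \code{"bed"} converts to BED's 0-based half-open
#'   convention (\code{start - 1}, \code{end}).
#' @return \code{path}, invisibly.
#' @export
write_intervals <- function(x, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "interval_set"))
  if (format == "tsv") {
    out <- data.frame(chrom = x$chrom, start = x$start, end = x$end)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Extract interval sequences from a genome
#'
#' Pulls the forward-strand, uppercase sequence of every interval from a
#' FASTA genome.  Sample ids encode \code{chrom:start-end}; labels are set
#' from the interval set's role (CORE sequences are the positive,
#' nucleosome class; LINKER sequences the negative class).  \code{N}
#' characters are retained (the motif scanner treats them as unmatchable).
#'
#' @param intervals an \code{\link{interval_set}}.
#' @param genome either a path to a FASTA file or a named
#'   \code{Biostrings::DNAStringSet} / named character vector of
#'   chromosome sequences.
#' @return A data frame of class \code{sequence_samples} with columns
#'   \code{id}, \code{label} (\code{"POSITIVE"} or \code{"NEGATIVE"}),
#'   \code{sequence} and \code{length}.
#' @export
extract_sequences <- function(intervals, genome) {
  stopifnot(inherits(intervals, "interval_set"))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    chroms <- vapply(as.character(genome), toupper, character(1))
  } else if (is.character(genome) && !is.null(names(genome))) {
    chroms <- toupper(genome)
  } else stop("'genome' must be a FASTA path or a named sequence set")
  # FASTA descriptions may carry trailing words; key on the first token
  names(chroms) <- sub("\\s.*$", "", names(chroms))
  missing <- setdiff(unique(intervals$chrom), names(chroms))
  if (length(missing))
    stop("chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  clen <- nchar(chroms)[intervals$chrom]
  over <- which(intervals$end > clen)
  if (length(over))
    stop("interval(s) beyond chromosome end: ",
         paste(sprintf("%s:%d-%d", intervals$chrom[over],
                       intervals$start[over], intervals$end[over])[
                         seq_len(min(5L, length(over)))], collapse = ", "))
  seqs <- substring(chroms[intervals$chrom], intervals$start, intervals$end)
  label <- if (interval_role(intervals) == "CORE") "POSITIVE" else "NEGATIVE"
  sequence_samples(
    id = sprintf("%s:%d-%d", intervals$chrom, intervals$start,
                 intervals$end),
    label = rep(label, nrow(intervals)),
    sequence = unname(seqs))
}

#' Construct a set of labeled sequence samples
#'
#' @param id character sample identifiers.
#' @param label per-sample class, \code{"POSITIVE"} (nucleosome core) or
#'   \code{"NEGATIVE"} (linker).
#' @param sequence DNA strings over \code{A,C,G,T,N}.
#' @return A data frame of class \code{sequence_samples}.
#' @export
sequence_samples <- function(id, label, sequence) {
  label <- as.character(label)
  stopifnot(length(id) == length(label), length(label) == length(sequence))
  if (length(label) && !all(label %in% c("POSITIVE", "NEGATIVE")))
    stop("labels must be POSITIVE or NEGATIVE")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("sequence(s) contain characters outside A,C,G,T,N: sample(s) ",
         paste(head(which(bad), 5L), collapse = ", "))
  structure(data.frame(id = as.character(id), label = label,
                       sequence = as.character(sequence),
                       length = nchar(sequence), stringsAsFactors = FALSE),
            class = c("sequence_samples", "data.frame"))
}

#' Write sequence samples as FASTA
#'
#' @param samples a \code{\link{sequence_samples}} data frame.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_sample_fasta <- function(samples, path) {
  stopifnot(inherits(samples, "sequence_samples"))
  x <- Biostrings::DNAStringSet(samples$sequence)
  names(x) <- samples$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
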