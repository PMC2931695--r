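#' Specification for a synthetic two-class feature matrix
#'
#' Describes the stochastic world the analysis assumes: positive
#' (nucleosome-core) samples of fixed 147 bp, negative (linker) samples
#' with geometric-like lengths (minimum \code{linker_min}, mean
#' \code{linker_mean}), and per-family motif-hit counts drawn with
#' expectation \code{rate * length}.  Informative families get
#' class-dependent per-bp rates; all other families use
#' \code{background_rate} in both classes.  The defaults plant 9
#' linker-enriched families among 35 with a 2-fold rate separation
#' (cores depleted to half the background density), mirroring the
#' biological expectation that TFBSs concentrate in accessible linker
#' DNA.
#'
#' @param n_pos,n_neg samples per class (default 2000 each).
#' @param n_features total families (default 35).
#' @param informative data frame with columns \code{index},
#'   \code{rate_pos}, \code{rate_neg} (expected hits per bp in each
#'   class); default: 9 evenly spaced families with
#'   \code{rate_pos = background_rate / 2},
#'   \code{rate_neg = background_rate}.
#' @param background_rate per-bp hit rate of non-informative families in
#'   both classes (default 0.01, about 1.5 hits per 147-bp core).
#' @param linker_min,linker_mean negative-sample length model: length =
#'   \code{linker_min + Geometric}, with mean \code{linker_mean}
#'   (defaults 6 and 38 bp).
#' @param count_model \code{"poisson"} (default) or \code{"nbinom"}
#'   (overdispersed, with \code{nb_size} the size parameter).
#' @param nb_size negative-binomial size when \code{count_model =
#'   "nbinom"} (default 5).
#' @param seed integer RNG seed; identical spec + seed gives identical
#'   output.
#' @return A list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_pos = 2000L, n_neg = 2000L, n_features = 35L,
                           informative = NULL, background_rate = 0.01,
                           linker_min = 6L, linker_mean = 38,
                           count_model = c("poisson", "nbinom"),
                           nb_size = 5, seed = 1L) {
  count_model <- match.arg(count_model)
  if (is.null(informative)) {
    idx <- unique(floor(seq(1L, n_features, length.out = min(9L, n_features))))
    informative <- data.frame(index = idx,
                              rate_pos = background_rate / 2,
                              rate_neg = background_rate)
  }
  stopifnot(all(c("index", "rate_pos", "rate_neg") %in% names(informative)))
  if (anyDuplicated(informative$index) ||
      any(informative$index < 1L) || any(informative$index > n_features))
    stop("informative indices must be distinct and within 1..n_features")
  if (any(informative$rate_pos < 0) || any(informative$rate_neg < 0) ||
      background_rate < 0)
    stop("rates must be >= 0")
  if (linker_mean <= linker_min)
    stop("linker_mean must exceed linker_min")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_features = as.integer(n_features),
                 informative = informative,
                 background_rate = background_rate,
                 linker_min = as.integer(linker_min),
                 linker_mean = linker_mean, count_model = count_model,
                 nb_size = nb_size, seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_counts <- function(n, mu, model, nb_size) {
  if (model == "poisson") rpois(n, mu) else rnbinom(n, size = nb_size,
                                                    mu = mu)
}

#' Generate a synthetic labeled feature matrix
#'
#' Per sample, draws a length from the class length model, then per
#' family a hit count with mean \code{rate * length}, and emits
#' \code{count / length}.  Labels are 1 (positive) and 2 (negative).
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A \code{\link{feature_matrix}} with attributes
#'   \code{informative} (the planted feature indices) and
#'   \code{lengths}.
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  labels <- rep(c(1L, 2L), c(spec$n_pos, spec$n_neg))
  lengths <- c(rep(147L, spec$n_pos),
               spec$linker_min +
                 rgeom(spec$n_neg,
                       prob = 1 / (spec$linker_mean - spec$linker_min + 1)))
  rates <- matrix(spec$background_rate, nrow = 2L, ncol = spec$n_features)
  rates[1L, spec$informative$index] <- spec$informative$rate_pos
  rates[2L, spec$informative$index] <- spec$informative$rate_neg
  if (all(rates == 0))
    warning("all rates are zero: the matrix will be degenerate")
  values <- matrix(0, n, spec$n_features,
                   dimnames = list(sprintf("S%05d", seq_len(n)),
                                   sprintf("F$S%02d",
                                           seq_len(spec$n_features))))
  for (j in seq_len(spec$n_features)) {
    mu <- rates[labels, j] * lengths
    values[, j] <- draw_counts(n, mu, spec$count_model, spec$nb_size) /
      lengths
  }
  fm <- feature_matrix(values, labels)
  attr(fm, "informative") <- spec$informative$index
  attr(fm, "lengths") <- lengths
  fm
}

# sample a concrete sequence from an IUPAC consensus
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                   Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                   K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

sample_consensus <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    s <- iupac_sets[[ch]]
    s[sample.int(length(s), 1L)]
  }, character(1)), collapse = "")
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Generate a toy genome with planted nucleosome cores and motifs
#'
#' Builds random chromosomes tiled by alternating linker gaps
#' (geometric-like lengths, minimum \code{linker_min}, mean
#' \code{linker_mean}) and 147-bp cores, then plants concrete instances
#' of the supplied motif families at class-dependent per-bp densities
#' (Poisson counts per region, uniform positions, random strand).  The
#' returned core table and genome feed \code{\link{load_core_sites}} /
#' \code{\link{derive_linkers}} / \code{\link{extract_sequences}}
#' end-to-end.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (each
#'   >= 200 bp).
#' @param families list of \code{\link{motif_family}} objects (consensus
#'   members only).
#' @param rate_core,rate_linker per-bp planting density per family inside
#'   cores and linkers; recycled over families.
#' @param linker_min,linker_mean gap-length model (defaults 6 and 38).
#' @param seed RNG seed.
#' @return List with \code{genome} (named character vector of chromosome
#'   sequences), \code{cores} and \code{linkers} (the planted
#'   \code{\link{interval_set}}s).
#' @export
generate_genome <- function(chrom_lengths, families, rate_core = 0.005,
                            rate_linker = 0.01, linker_min = 6L,
                            linker_mean = 38, seed = 1L) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  if (any(chrom_lengths < 200L))
    stop("chromosome lengths must be >= 200 bp")
  if (linker_mean <= linker_min)
    stop("spacing model incompatible: linker_mean must exceed linker_min")
  set.seed(seed)
  rate_core <- rep_len(rate_core, length(families))
  rate_linker <- rep_len(rate_linker, length(families))
  gp <- 1 / (linker_mean - linker_min + 1)
  genome <- character(0)
  core_rows <- list(); linker_rows <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    pos <- 0L                      # last covered position
    cores <- NULL; linkers <- NULL
    repeat {
      gap <- linker_min + rgeom(1L, gp)
      if (pos + gap + 147L > L) break
      if (!is.null(cores))         # interior gap only
        linkers <- rbind(linkers, c(pos + 1L, pos + gap))
      cores <- rbind(cores, c(pos + gap + 1L, pos + gap + 147L))
      pos <- pos + gap + 147L
    }
    if (is.null(cores)) next
    plant <- function(lo, hi, rate) {
      len <- hi - lo + 1L
      for (k in seq_along(families)) {
        fam <- families[[k]]
        n_inst <- rpois(1L, rate[k] * len)
        for (i in seq_len(n_inst)) {
          memb <- fam$members[[sample.int(length(fam$members), 1L)]]
          if (!is.character(memb))
            stop("generate_genome supports consensus members only")
          inst <- sample_consensus(memb)
          if (runif(1) < 0.5) inst <- revcomp_chr(inst)
          w <- nchar(inst)
          if (w > len) next
          at <- lo + sample.int(len - w + 1L, 1L) - 1L
          seqv[at:(at + w - 1L)] <<- strsplit(inst, "")[[1]]
        }
      }
    }
    for (r in seq_len(nrow(cores)))
      plant(cores[r, 1L], cores[r, 2L], rate_core)
    if (!is.null(linkers))
      for (r in seq_len(nrow(linkers)))
        plant(linkers[r, 1L], linkers[r, 2L], rate_linker)
    genome[chrom] <- paste(seqv, collapse = "")
    core_rows[[chrom]] <- data.frame(chrom = chrom, start = cores[, 1L],
                                     end = cores[, 2L])
    if (!is.null(linkers))
      linker_rows[[chrom]] <- data.frame(chrom = chrom,
                                         start = linkers[, 1L],
                                         end = linkers[, 2L])
  }
  cd <- do.call(rbind, core_rows)
  ld <- do.call(rbind, linker_rows)
  list(genome = genome,
       cores = interval_set(cd$chrom, cd$start, cd$end, role = "CORE"),
       linkers = if (is.null(ld))
         interval_set(character(), integer(), integer(), role = "LINKER")
       else interval_set(ld$chrom, ld$start, ld$end, role = "LINKER"))
}
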