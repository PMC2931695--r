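# feature_matrix: motif scanning, matrix construction, file dialect

test_that("scan_family_hits counts both strands with overlaps", {
  fam <- motif_family("F$TOY", "ACGT")
  # 2 forward + 2 reverse-complement hits (ACGT is its own revcomp)
  expect_identical(scan_family_hits("ACGTACGT", fam), 4L)
  expect_identical(scan_family_hits("AAAA", motif_family("F$X", "CGCG")), 0L)
  # member longer than the sequence
  expect_identical(scan_family_hits("ACG", motif_family("F$X", "ACGTACGT")),
                   0L)
  # overlapping matches are all counted (3 forward starts; revcomp TT
  # finds nothing)
  expect_identical(scan_family_hits("AAAA", motif_family("F$A", "AA")), 3L)
  expect_identical(oracle_scan("AAAA", "AA"), 3L)
  expect_error(scan_family_hits("", fam), "non-empty")
})

test_that("same-position same-strand hits of several members count once", {
  # both members match forward at position 2 and reverse with 5' at 5
  fam <- motif_family("F$U", c("ACGT", "ACG"))
  expect_identical(scan_family_hits("AACGTT", fam),
                   oracle_scan("AACGTT", c("ACGT", "ACG")))
  expect_identical(oracle_scan("AACGTT", c("ACGT", "ACG")), 2L)
})

test_that("IUPAC degeneracy matches and N never matches", {
  fam <- motif_family("F$GATA", "WGATAR")
  expect_identical(scan_family_hits("TGATAA", fam), 1L)
  expect_identical(scan_family_hits("CGATAA", fam), 0L)
  expect_identical(scan_family_hits("TGANAA", fam), 0L)   # N blocks the hit
  # even an all-N pattern cannot match across an N base
  expect_identical(scan_family_hits("ANGT", motif_family("F$N", "NN")),
                   oracle_scan("ANGT", "NN"))
})

test_that("scanner agrees with the exhaustive oracle on random inputs", {
  set.seed(13)
  pats <- c("WGATAR", "CACGTG", "TTAGGG", "RYRY", "GCN")
  for (i in 1:12) {
    seqs <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                         prob = c(.24, .24, .24, .24, .04)), collapse = "")
    members <- sample(pats, sample(1:3, 1))
    fam <- motif_family("F$RND", members)
    expect_identical(scan_family_hits(seqs, fam),
                     oracle_scan(seqs, members))
    # strand symmetry: count equals count on the reverse complement
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqs)))
    expect_identical(scan_family_hits(seqs, fam),
                     scan_family_hits(rc, fam))
  }
})

test_that("PWM members are scanned through matchPWM", {
  pwm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["A", 1] <- pwm["C", 2] <- pwm["G", 3] <- pwm["T", 4] <- 1
  fam <- motif_family("F$PWM", list(pwm), pwm_min_score = "99%")
  expect_identical(scan_family_hits("ACGTACGT", fam), 4L)
})

test_that("build_matrix normalizes counts by sequence length", {
  fams <- list(motif_family("F$A", "AA"), motif_family("F$C", "CC"))
  samples <- sequence_samples(
    id = c("s1", "s2"),
    label = c("POSITIVE", "NEGATIVE"),
    sequence = c("AAAG", "GCCG"))
  fm <- build_matrix(samples, fams)
  # s1 "AAAG": AA forward at 1,2; revcomp TT absent -> 2 hits, value 2/4
  expect_identical(unname(fm$values[1, ]), c(2/4, 0))
  expect_identical(unname(fm$values[1, 1]),
                   oracle_scan("AAAG", "AA") / 4)
  expect_identical(unname(fm$values[2, ]),
                   c(oracle_scan("GCCG", "AA") / 4,
                     oracle_scan("GCCG", "CC") / 4))
  expect_identical(fm$labels, c(1L, 2L))
  expect_identical(family_names(fm), c("F$A", "F$C"))

  # all-zero row for a hitless sample
  s0 <- sequence_samples("z", "NEGATIVE", "GGGG")
  expect_true(all(build_matrix(s0, list(motif_family("F$A", "AA")))$values
                  == 0))
})

test_that("column count equals family count and values scale linearly", {
  fams <- lapply(1:5, function(i) motif_family(sprintf("F$%d", i), "CACGTG"))
  s <- sequence_samples(c("a", "b"), c("POSITIVE", "NEGATIVE"),
                        c(strrep("CACGTG", 1), strrep("CACGTG", 2)))
  fm <- build_matrix(s, fams)
  expect_identical(ncol(fm$values), 5L)
  # b has twice the hits of a but also twice the length: doubling hit
  # count at fixed length doubles the value
  one_len <- scan_family_hits(strrep("CACGTGAAAAAA", 1), fams[[1]])
  two_len <- scan_family_hits(paste0("CACGTGCACGTG", strrep("A", 0)),
                              fams[[1]])
  expect_identical(two_len, 2L * one_len + 0L)
})

test_that("matrix file dialect round-trips and reports parse errors", {
  fm <- make_toy_fm(8, 8, rates_pos = c(.2, .05), rates_neg = c(.05, .2),
                    seed = 3)
  fm$values[1, 1] <- 1 / 3        # exercise long decimals
  p <- withr::local_tempfile(fileext = ".txt")
  write_matrix(fm, p)
  back <- read_matrix(p)
  expect_identical(back$labels, fm$labels)
  expect_identical(family_names(back), family_names(fm))
  expect_equal(back$values, fm$values, tolerance = 1e-12,
               ignore_attr = TRUE)

  # headerless files are accepted too
  write_matrix(fm, p, header = FALSE)
  back2 <- read_matrix(p)
  expect_identical(back2$labels, fm$labels)
  expect_equal(unname(back2$values), unname(fm$values), tolerance = 1e-12)

  # degenerate and malformed inputs
  pe <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), pe)
  expect_error(read_matrix(pe), "empty")
  writeLines(c("1\t0.5\t0.25", "2\t0.1\tabc"), pe)
  expect_error(read_matrix(pe), "line 2")
  writeLines(c("1\t0.5", "3\t0.1"), pe)
  expect_error(read_matrix(pe), "label.*line 2")
})

test_that("feature_matrix validates its invariants", {
  expect_error(feature_matrix(matrix(1, 2, 2), c(1L, 3L)), "labels")
  expect_error(feature_matrix(matrix(-1, 2, 2), c(1L, 2L)), "finite")
  expect_error(feature_matrix(matrix(1, 2, 2), c(1L)), "label count")
  m <- matrix(1, 2, 2, dimnames = list(NULL, c("A", "A")))
  expect_error(feature_matrix(m, c(1L, 2L)), "unique")
  expect_error(select_features(make_toy_fm(4, 4, .1, .1), "F$NOPE"),
               "unknown feature")
})

test_that("motif definition files load family groupings", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\tmember_id\tpattern",
               "F$GATA\tGATA1\tWGATAR",
               "F$GATA\tGATA2\tGATA",
               "F$EBOX\tEBOX1\tCACGTG"), p)
  fams <- read_motif_families(p)
  expect_identical(names(fams), c("F$GATA", "F$EBOX"))
  expect_identical(length(fams[["F$GATA"]]$members), 2L)
  expect_error(motif_family("F$BAD", character(0)), "no members")
  expect_error(motif_family("F$BAD", "ACGU"), "IUPAC")
})
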