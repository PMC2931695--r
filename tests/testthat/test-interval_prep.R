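# interval_prep: core-site loading, linker derivation, sequence extraction

test_that("load_core_sites parses, sorts and validates coordinate tables", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_fixture(data.frame(chrom = c("chrI", "chrI"),
                               start = c(100L, 50L),
                               end = c(246L, 196L)), p)
  x <- load_core_sites(p)
  expect_s3_class(x, "interval_set")
  expect_identical(x$start, c(50L, 100L))        # sorting contract
  expect_identical(x$end, c(196L, 246L))
  expect_identical(attr(x, "role"), "CORE")
  expect_true(all(x$length == 147L))

  # empty table -> empty set
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), p2)
  expect_identical(nrow(load_core_sites(p2)), 0L)

  # comma-separated, headerless
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chrII,10,156", "chrI,5,151"), p3)
  x3 <- load_core_sites(p3)
  expect_identical(x3$chrom, c("chrI", "chrII"))

  # malformed rows are rejected with row numbers
  p4 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_fixture(data.frame(chrom = "chrI", start = 200L, end = 100L), p4)
  expect_error(load_core_sites(p4), "end < start.*1")
  p5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend", "chrI\tabc\t100"), p5)
  expect_error(load_core_sites(p5), "non-numeric")
  p6 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrI\t100", p6)
  expect_error(load_core_sites(p6), ">= 3 columns")
})

test_that("derive_linkers emits interior gaps under length filters", {
  cores <- interval_set(c("chrI", "chrI"), c(1L, 160L), c(147L, 306L),
                        role = "CORE")
  lk <- derive_linkers(cores)
  expect_identical(nrow(lk), 1L)
  expect_identical(lk$start, 148L)
  expect_identical(lk$end, 159L)
  expect_identical(lk$length, 12L)
  expect_identical(attr(lk, "role"), "LINKER")

  # gap of 4 < min_len 6 -> dropped
  cores2 <- interval_set(c("chrI", "chrI"), c(1L, 152L), c(147L, 298L),
                         role = "CORE")
  expect_identical(nrow(derive_linkers(cores2)), 0L)
  expect_identical(nrow(derive_linkers(cores2, min_len = 4L)), 1L)

  # max_len cap and cross-chromosome separation; no terminal gaps
  cores3 <- interval_set(c("chrI", "chrI", "chrII", "chrII"),
                         c(100L, 400L, 1L, 500L),
                         c(246L, 546L, 147L, 646L), role = "CORE")
  lk3 <- derive_linkers(cores3)
  expect_identical(nrow(lk3), 2L)            # one per chromosome, interior
  expect_identical(lk3$chrom, c("chrI", "chrII"))
  lk3c <- derive_linkers(cores3, max_len = 200L)
  expect_identical(lk3c$chrom, "chrI")       # chrII gap (352 bp) capped out

  # overlapping / book-ended cores yield no linker
  cores4 <- interval_set(c("chrI", "chrI"), c(1L, 100L), c(147L, 246L),
                         role = "CORE")
  expect_identical(nrow(derive_linkers(cores4, min_len = 1L)), 0L)
  expect_error(derive_linkers(lk, min_len = 1L), "role CORE")
})

test_that("cores and linkers tile the inter-core span (properties)", {
  set.seed(7)
  for (rep in 1:5) {
    # random non-overlapping cores on one chromosome
    n <- sample(5:25, 1)
    gaps <- sample(0:300, n, replace = TRUE)
    starts <- cumsum(gaps + 147L) - 146L
    cores <- interval_set(rep("chrX", n), starts, starts + 146L,
                          role = "CORE")
    lk <- derive_linkers(cores, min_len = 1L)
    # conservation: linker lengths fill the span minus the cores
    span <- max(cores$end) - min(cores$start) + 1L
    expect_identical(sum(lk$length) + sum(cores$length), span)
    # complementarity: sorted pieces are contiguous and non-overlapping
    pieces <- rbind(data.frame(s = cores$start, e = cores$end),
                    data.frame(s = lk$start, e = lk$end))
    pieces <- pieces[order(pieces$s), ]
    expect_true(all(pieces$s[-1] == pieces$e[-nrow(pieces)] + 1L))
  }
})

test_that("derive_linkers is invariant to input row order", {
  df <- data.frame(chrom = c("chrI", "chrII", "chrI"),
                   start = c(200L, 50L, 1L), end = c(346L, 196L, 147L))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_fixture(df, p1)
  write_tsv_fixture(df[c(3, 1, 2), ], p2)
  expect_identical(as.data.frame(derive_linkers(load_core_sites(p1))),
                   as.data.frame(derive_linkers(load_core_sites(p2))))
})

test_that("extract_sequences follows 1-based inclusive coordinates", {
  genome <- c(chrA = "AAACCC", chrB = "acgtacgtacgt")
  iv <- interval_set("chrA", 4L, 6L, role = "CORE")
  s <- extract_sequences(iv, genome)
  expect_identical(s$sequence, "CCC")          # direct indexing oracle
  expect_identical(s$label, "POSITIVE")
  expect_identical(s$id, "chrA:4-6")

  iv2 <- interval_set("chrB", 1L, 4L, role = "LINKER")
  s2 <- extract_sequences(iv2, genome)
  expect_identical(s2$sequence, "ACGT")        # uppercased forward strand
  expect_identical(s2$label, "NEGATIVE")
  expect_identical(s2$length, 4L)

  # out-of-range and unknown chromosome errors name the interval
  expect_error(extract_sequences(interval_set("chrA", 2L, 9L, role = "CORE"),
                                 genome), "chrA:2-9")
  expect_error(extract_sequences(interval_set("chrZ", 1L, 3L, role = "CORE"),
                                 genome), "chrZ")
})

test_that("extraction round-trips through FASTA and preserves lengths", {
  set.seed(11)
  chrom <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrI toy assembly", substring(chrom, 1, 80),
               substring(chrom, 81, 400)), fa)
  iv <- interval_set(rep("chrI", 2), c(10L, 200L), c(156L, 346L),
                     role = "CORE")
  s <- extract_sequences(iv, fa)
  expect_identical(s$length, c(147L, 147L))    # length conservation
  expect_identical(s$sequence[1], substring(chrom, 10, 156))
  out <- withr::local_tempfile(fileext = ".fa")
  write_sample_fasta(s, out)
  back <- Biostrings::readDNAStringSet(out)
  expect_identical(unname(as.character(back)), s$sequence)
})

test_that("interval TSV and BED exports use the right conventions", {
  iv <- interval_set("chrI", 148L, 159L, role = "LINKER")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_intervals(iv, p, "tsv")
  expect_identical(read.table(p, header = TRUE)$start, 148L)
  b <- withr::local_tempfile(fileext = ".bed")
  write_intervals(iv, b, "bed")
  bed <- read.table(b)
  expect_identical(bed$V2, 147L)               # 0-based half-open
  expect_identical(bed$V3, 159L)
})
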