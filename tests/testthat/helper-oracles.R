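# Independent oracles: deliberately naive re-implementations used to
# cross-check the package's optimized code paths.  They share no code with
# the package internals.

# cosine distance with the documented zero-norm conventions
oracle_cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 && ny == 0) return(0)
  if (nx == 0 || ny == 0) return(1)
  1 - sum(x * y) / (nx * ny)
}

# double-loop leave-one-out nearest neighbor: per-sample predicted labels.
# Distances are compared at 12-decimal precision, the package's documented
# canonicalization (summation-order ulp noise must not decide ties).
oracle_loo_predictions <- function(values, labels) {
  n <- nrow(values)
  pred <- integer(n)
  for (i in seq_len(n)) {
    best_d <- Inf; best_j <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- round(oracle_cosine(values[i, ], values[j, ]), 12)
      if (d < best_d) { best_d <- d; best_j <- j }
    }
    pred[i] <- labels[best_j]
  }
  pred
}

# brute-force mutual information of a contingency table (explicit sum)
oracle_mi_table <- function(tab, base = 2) {
  n <- sum(tab)
  acc <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0)
      acc <- acc + (nij / n) *
        log((nij / n) / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)),
            base = base)
  }
  acc
}

oracle_mi <- function(x, y, base = 2) oracle_mi_table(table(x, y), base)

# greedy-by-hand mRMR (MID criterion) over pre-discretized state vectors
oracle_mrmr_order <- function(disc_list, labels, base = 2) {
  nf <- length(disc_list)
  rel <- vapply(disc_list, oracle_mi, numeric(1), y = labels, base = base)
  selected <- integer(0)
  candidates <- seq_len(nf)
  while (length(candidates)) {
    score <- vapply(candidates, function(j) {
      if (!length(selected)) return(rel[j])
      red <- mean(vapply(selected, function(s)
        oracle_mi(disc_list[[j]], disc_list[[s]], base = base), numeric(1)))
      rel[j] - red
    }, numeric(1))
    pick <- candidates[which.max(score)]
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
  }
  selected
}

# exhaustive both-strand overlapping scan of IUPAC consensus members,
# counting distinct 5' positions per strand (regex-based, no Biostrings)
oracle_scan <- function(sequence, members) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
             S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
             D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  hits_fwd <- integer(0); hits_rev <- integer(0)
  for (m in members) {
    pc <- strsplit(toupper(m), "")[[1]]
    w <- length(pc)
    if (w > L) next
    rc <- rev(unname(comp[pc]))
    for (s in seq_len(L - w + 1L)) {
      win <- chars[s:(s + w - 1L)]
      if (all(mapply(function(p, ch) grepl(iupac[[p]], ch, fixed = FALSE),
                     pc, win)))
        hits_fwd <- c(hits_fwd, s)
      if (all(mapply(function(p, ch) grepl(iupac[[p]], ch, fixed = FALSE),
                     rc, win)))
        hits_rev <- c(hits_rev, s + w - 1L)   # 5' end on reverse strand
    }
  }
  length(unique(hits_fwd)) + length(unique(hits_rev))
}

# a small well-behaved feature matrix of Poisson counts / fixed length
make_toy_fm <- function(n_pos = 30, n_neg = 30, rates_pos, rates_neg,
                        len = 100, seed = 1) {
  set.seed(seed)
  nf <- length(rates_pos)
  vp <- sapply(seq_len(nf), function(j) rpois(n_pos, rates_pos[j] * len))
  vn <- sapply(seq_len(nf), function(j) rpois(n_neg, rates_neg[j] * len))
  v <- rbind(vp, vn) / len
  colnames(v) <- sprintf("F$T%02d", seq_len(nf))
  feature_matrix(v, rep(c(1L, 2L), c(n_pos, n_neg)))
}

# the three-feature mRMR toy: f1 informative, f2 = exact copy of f1,
# f3 weakly informative and independent of f1 after discretization
mrmr_toy <- function() {
  f1 <- c(9, 9, 1, 1, 5, 5, 5, 5)   # states H H L L M M M M
  f3 <- c(9, 5, 5, 5, 5, 5, 5, 5)   # states H M M M M M M M
  v <- cbind(f1 = f1, f2 = f1, f3 = f3)
  feature_matrix(v, c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
}

write_tsv_fixture <- function(df, path, col.names = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  path
}
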