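# Independent oracles used to cross-check the package's engines.  These are
# deliberately separate implementations: their own parameter-table literals,
# plain loops instead of the vectorized production paths.

.o_comp <- function(x) chartr("ACGT", "TGCA", x)
o_revcomp <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(.o_comp(s), "")[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

.o_fill <- function(tbl) {
  out <- tbl
  for (d in names(tbl)) out[o_revcomp(d)] <- tbl[d]
  out
}

.O_DH <- .o_fill(c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
                   CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0))
.O_DS <- .o_fill(c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
                   GT = -22.4, CT = -21.0, GA = -22.2, CG = -27.2,
                   GC = -24.4, GG = -19.9))
.O_BRES <- .o_fill(c(AA = -1.9, AT = -1.5, TA = -0.9, CA = -1.9, GT = -1.3,
                     CT = -1.6, GA = -1.6, CG = -3.6, GC = -3.1, GG = -3.1))

# hand summation of the nearest-neighbor tables; match = NULL means a perfect
# duplex, otherwise a logical vector marking matched positions
oracle_tm <- function(seq, na_mM = 50, conc_nM = 250, match = NULL) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  if (is.null(match)) match <- rep(TRUE, n)
  dH <- 0; dS <- 0
  for (i in seq_len(n - 1)) {
    if (match[i] && match[i + 1]) {
      d <- paste0(b[i], b[i + 1])
      dH <- dH + .O_DH[[d]]; dS <- dS + .O_DS[[d]]
    }
  }
  for (t in c(b[1], b[n])) {
    if (t %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                    { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  denom <- dS + 1.987 * log(conc_nM * 1e-9 / 4)
  if (dH >= 0 || denom >= 0) return(-273.15)
  dH * 1000 / denom - 273.15
}

oracle_dg3 <- function(primer) {
  b <- strsplit(primer, "")[[1]]
  p <- b[(length(b) - 4):length(b)]
  sum(vapply(1:4, function(i) .O_BRES[[paste0(p[i], p[i + 1])]], numeric(1)))
}

# exhaustive sliding-window binding-site scan over one chromosome string
oracle_sites <- function(primer, chrom_id, chrom, word_size = 4,
                         min_tm = 50) {
  L <- nchar(primer)
  glen <- nchar(chrom)
  pb <- strsplit(primer, "")[[1]]
  rcp <- o_revcomp(primer)
  rb <- strsplit(rcp, "")[[1]]
  cb <- strsplit(chrom, "")[[1]]
  out <- list()
  for (s in seq_len(glen - L + 1)) {
    win <- cb[s:(s + L - 1)]
    # plus strand: 3' seed = last word_size positions
    m <- win == pb
    if (all(m[(L - word_size + 1):L]) && !any(win == "N")) {
      tm <- oracle_tm(primer, match = m)
      if (tm >= min_tm)
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom_id, strand = "+", start = s - 1L, end = s + L - 1L,
          matched_bases = sum(m), duplex_tm = tm)
    }
    # minus strand: revcomp(primer) along template, seed = first positions
    m <- win == rb
    if (all(m[1:word_size]) && !any(win == "N")) {
      tm <- oracle_tm(rcp, match = m)
      if (tm >= min_tm)
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom_id, strand = "-", start = s - 1L, end = s + L - 1L,
          matched_bases = sum(m), duplex_tm = tm)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# brute-force pairing of oracle sites into amplicons
oracle_amplicons <- function(fwd, rev, chroms, max_bp = 10000,
                             ppc_cutoff = 0.3, min_tm = 50, word_size = 4) {
  out <- list()
  lf <- nchar(fwd); lr <- nchar(rev)
  for (id in names(chroms)) {
    fs <- oracle_sites(fwd, id, chroms[[id]], word_size, min_tm)
    rs <- oracle_sites(rev, id, chroms[[id]], word_size, min_tm)
    if (is.null(fs) || is.null(rs)) next
    fs <- fs[fs$strand == "+", , drop = FALSE]
    rs <- rs[rs$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
      size <- rs$end[j] - fs$start[i]
      ppc <- (fs$matched_bases[i] / lf + rs$matched_bases[j] / lr) / 2
      if (size >= lf + lr && size <= max_bp && ppc >= ppc_cutoff)
        out[[length(out) + 1]] <- data.frame(
          chrom = id, start = fs$start[i], end = rs$end[j], size = size)
    }
  }
  if (length(out) == 0) return(NULL)
  amp <- do.call(rbind, out)
  amp[order(amp$chrom, amp$start, amp$end), ]
}

# plain Needleman-Wunsch DP with linear gaps; returns identity in percent
# (matches over alignment length) of one optimal traceback
oracle_nw_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (A[i] == B[j]) match else mismatch,
      S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  i <- n; j <- m; matches <- 0; alen <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + if (A[i] == B[j]) match else mismatch) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    alen <- alen + 1
  }
  100 * matches / alen
}

# exhaustive ungapped search: does any window of length >= min_len on any
# diagonal of any strand have identity strictly above min_id?  O(L^2) per
# diagonal, checking every (start, end) pair explicitly.
oracle_has_hit <- function(amp, gene_seq, min_id = 0.80, min_len = 200) {
  for (g in c(gene_seq, o_revcomp(gene_seq))) {
    La <- nchar(amp); Lg <- nchar(g)
    for (d in (-(La - 1)):(Lg - 1)) {
      i1 <- max(1, 1 - d); i2 <- min(La, Lg - d)
      if (i2 - i1 + 1 < min_len) next
      m <- strsplit(substr(amp, i1, i2), "")[[1]] ==
        strsplit(substr(g, i1 + d, i2 + d), "")[[1]]
      cs <- c(0, cumsum(m))
      n <- length(m)
      for (s in 1:(n - min_len + 1)) for (e in (s + min_len - 1):n) {
        if ((cs[e + 1] - cs[s]) > min_id * (e - s + 1)) return(TRUE)
      }
    }
  }
  FALSE
}

# fast exact equivalent of the exhaustive window check (prefix-sum
# transform), for use on larger fixtures where O(L^2) is too slow
oracle_has_hit_fast <- function(amp, gene_seq, min_id = 0.80,
                                min_len = 200) {
  for (g in c(gene_seq, o_revcomp(gene_seq))) {
    La <- nchar(amp); Lg <- nchar(g)
    for (d in (-(La - 1)):(Lg - 1)) {
      i1 <- max(1, 1 - d); i2 <- min(La, Lg - d)
      n <- i2 - i1 + 1
      if (n < min_len) next
      m <- strsplit(substr(amp, i1, i2), "")[[1]] ==
        strsplit(substr(g, i1 + d, i2 + d), "")[[1]]
      D <- c(0, cumsum(100 * as.integer(m) - as.integer(100 * min_id)))
      best <- Inf
      for (j in min_len:n) {
        best <- min(best, D[j - min_len + 1])
        if (D[j + 1] - best > 0) return(TRUE)
      }
    }
  }
  FALSE
}

o_rand_dna <- function(n, at = 0.56) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# tiny deterministic genome + gene table for unit fixtures
small_genome_fixture <- function(seed = 11) {
  generate_genome(n_chrom = 2, genes_per_chrom = 8,
                  gene_len_range = c(420, 700),
                  intergenic_len_range = c(100, 200),
                  n_paralog_pairs = 1, paralog_identity = 0.96,
                  n_retired = 2, desert_len = 2200, seed = seed)
}
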