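# Desk-scale in-silico PCR: seed-anchored binding-site discovery, duplex Tm
# at mismatched sites, amplicon enumeration with size / Tm / pair-coverage
# filters, and the intrinsic primer-pair quality flags.
#
# A binding site requires the primer's 3'-terminal word (default 4 nt, the
# stringent MFEprimer-style word size) to match the template exactly --
# polymerase extension tolerates no 3'-terminal mismatch -- while positions
# 5' of the seed may mismatch.  Mismatched positions contribute no
# nearest-neighbor stack to the site's duplex Tm, so the Tm is monotone in
# the number of matched bases.

.empty_sites <- function() {
  data.frame(chrom = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             matched_bases = integer(0), duplex_tm = numeric(0),
             stringsAsFactors = FALSE)
}

# vectorized duplex Tm for a match matrix M (sites x primer length), stacks
# taken from `seq_chars` orientation (the strand-local primer sequence)
.site_tms <- function(M, seq_chars, thermo) {
  L <- length(seq_chars)
  ids <- paste0(seq_chars[-L], seq_chars[-1])
  h <- .NN_UNIFIED_DH[ids]; s <- .NN_UNIFIED_DS[ids]
  K <- M[, -L, drop = FALSE] & M[, -1L, drop = FALSE]
  dH <- as.vector(K %*% h)
  dS <- as.vector(K %*% s)
  for (term in seq_chars[c(1L, L)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (L - 1) * log(thermo$monovalent_mM / 1000)
  denom <- dS + .GAS_CONSTANT * log(thermo$primer_conc_nM * 1e-9 / 4)
  tm <- ifelse(dH >= 0 | denom >= 0, -273.15, dH * 1000 / denom - 273.15)
  tm
}

.sites_one_chrom <- function(primer, chrom_id, subject, word_size,
                             min_duplex_tm, thermo) {
  L <- nchar(primer)
  pchars <- strsplit(primer, "", fixed = TRUE)[[1]]
  rcp <- reverse_complement(primer)
  rchars <- strsplit(rcp, "", fixed = TRUE)[[1]]
  out <- list()

  # plus strand: primer lies along the template, 3' end rightmost
  seed <- substr(primer, L - word_size + 1L, L)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(seed), subject)
  ends <- BiocGenerics::end(hits)
  starts1 <- ends - L + 1L                      # 1-based footprint start
  keep <- starts1 >= 1L
  if (any(keep)) {
    v <- Biostrings::Views(subject, start = starts1[keep], end = ends[keep])
    M <- suppressWarnings(as.matrix(v)) == matrix(pchars, nrow = sum(keep), ncol = L,
                                byrow = TRUE)
    tm <- .site_tms(M, pchars, thermo)
    ok <- tm >= min_duplex_tm
    if (any(ok))
      out[["+"]] <- data.frame(chrom = chrom_id, strand = "+",
                               start = starts1[keep][ok] - 1L,
                               end = ends[keep][ok],
                               matched_bases = rowSums(M)[ok],
                               duplex_tm = tm[ok], stringsAsFactors = FALSE)
  }

  # minus strand: reverse complement lies along the template, primer 3' end
  # at the leftmost footprint base
  rseed <- substr(rcp, 1L, word_size)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(rseed), subject)
  starts1 <- BiocGenerics::start(hits)
  ends <- starts1 + L - 1L
  keep <- ends <= length(subject)
  if (any(keep)) {
    v <- Biostrings::Views(subject, start = starts1[keep], end = ends[keep])
    M <- suppressWarnings(as.matrix(v)) == matrix(rchars, nrow = sum(keep), ncol = L,
                                byrow = TRUE)
    tm <- .site_tms(M, rchars, thermo)
    ok <- tm >= min_duplex_tm
    if (any(ok))
      out[["-"]] <- data.frame(chrom = chrom_id, strand = "-",
                               start = starts1[keep][ok] - 1L,
                               end = ends[keep][ok],
                               matched_bases = rowSums(M)[ok],
                               duplex_tm = tm[ok], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) .empty_sites() else do.call(rbind, out)
}

#' Find primer binding sites on a genome
#'
#' Scans both strands of every chromosome for footprints whose 3'-terminal
#' `word_size` bases match the template exactly and whose mismatch-aware
#' duplex melting temperature reaches `min_duplex_tm`.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param word_size Length of the exact 3'-terminal seed (default 4).
#' @param min_duplex_tm Minimum site duplex Tm in Celsius (default 50, the
#'   working threshold for a 58 degree annealing protocol).
#' @param thermo A [thermo_params()].
#' @return A data.frame of sites: `chrom, strand, start, end` (0-based
#'   half-open template footprint), `matched_bases, duplex_tm`.
#' @export
find_binding_sites <- function(primer, genome, word_size = 4,
                               min_duplex_tm = 50,
                               thermo = thermo_params()) {
  primer <- .check_dna(primer, "primer")
  if (word_size > nchar(primer)) stop("word_size exceeds primer length")
  res <- lapply(seq_along(genome), function(i) {
    .sites_one_chrom(primer, names(genome)[i], genome[[i]], word_size,
                     min_duplex_tm, thermo)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.empty_amplicons <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             size = integer(0), fwd_tm = numeric(0), rev_tm = numeric(0),
             fwd_matched = integer(0), rev_matched = integer(0),
             ppc = numeric(0), stringsAsFactors = FALSE)
}

#' Enumerate predicted PCR products of a primer pair
#'
#' Pairs every plus-strand site of the forward primer with every downstream
#' minus-strand site of the reverse primer on the same chromosome.  Retained
#' products satisfy `size <= max_amplicon_bp`, `size >= `sum of primer
#' lengths, both site Tm values `>= min_duplex_tm`, and a pair-coverage score
#' `ppc = (m_f/l_f + m_r/l_r)/2 >= ppc_cutoff` (the mean fraction of matched
#' primer bases across the pair).
#'
#' @param fwd,rev Forward and reverse primer sequences, 5'->3'.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param max_amplicon_bp Largest product size considered amplifiable
#'   (default 10000).
#' @param ppc_cutoff Minimum pair coverage (default 0.3).
#' @inheritParams find_binding_sites
#' @return A data.frame of amplicons sorted by `(chrom, start)`: `chrom,
#'   start, end, size, fwd_tm, rev_tm, fwd_matched, rev_matched, ppc`.
#' @export
enumerate_amplicons <- function(fwd, rev, genome, max_amplicon_bp = 10000,
                                ppc_cutoff = 0.3, min_duplex_tm = 50,
                                word_size = 4, thermo = thermo_params()) {
  fs <- find_binding_sites(fwd, genome, word_size, min_duplex_tm, thermo)
  fs <- fs[fs$strand == "+", , drop = FALSE]
  rs <- find_binding_sites(rev, genome, word_size, min_duplex_tm, thermo)
  rs <- rs[rs$strand == "-", , drop = FALSE]
  lf <- nchar(fwd); lr <- nchar(rev)
  if (nrow(fs) == 0L || nrow(rs) == 0L) return(.empty_amplicons())
  out <- list()
  for (ch in intersect(unique(fs$chrom), unique(rs$chrom))) {
    f <- fs[fs$chrom == ch, ]; r <- rs[rs$chrom == ch, ]
    idx <- expand.grid(i = seq_len(nrow(f)), j = seq_len(nrow(r)))
    size <- r$end[idx$j] - f$start[idx$i]
    ppc <- (f$matched_bases[idx$i] / lf + r$matched_bases[idx$j] / lr) / 2
    keep <- size >= (lf + lr) & size <= max_amplicon_bp & ppc >= ppc_cutoff
    if (any(keep)) {
      k <- which(keep)
      out[[ch]] <- data.frame(
        chrom = ch, start = f$start[idx$i[k]], end = r$end[idx$j[k]],
        size = size[k], fwd_tm = f$duplex_tm[idx$i[k]],
        rev_tm = r$duplex_tm[idx$j[k]],
        fwd_matched = f$matched_bases[idx$i[k]],
        rev_matched = r$matched_bases[idx$j[k]],
        ppc = ppc[k], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(.empty_amplicons())
  amp <- do.call(rbind, out)
  amp <- amp[order(amp$chrom, amp$start, amp$end), ]
  rownames(amp) <- NULL
  amp
}

#' Extract amplicon sequences from the genome
#'
#' @param amplicons An amplicon table from [enumerate_amplicons()].
#' @param genome A named [Biostrings::DNAStringSet].
#' @return Character vector of plus-strand amplicon sequences.
#' @export
amplicon_sequences <- function(amplicons, genome) {
  vapply(seq_len(nrow(amplicons)), function(i) {
    as.character(Biostrings::subseq(genome[[amplicons$chrom[i]]],
                                    start = amplicons$start[i] + 1L,
                                    end = amplicons$end[i]))
  }, character(1))
}

#' Intrinsic quality flags of a primer pair
#'
#' Flags pairs violating the efficiency criteria (each primer Tm above 50
#' degrees; forward/reverse Tm difference below 3 degrees).  Flags are
#' informational and carry no score penalty.
#'
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param thermo A [thermo_params()].
#' @return Character vector, a subset of
#'   `c("TM_LOW_FWD", "TM_LOW_REV", "TM_IMBALANCE")`.
#' @export
primer_pair_flags <- function(fwd, rev, thermo = thermo_params()) {
  tf <- tm_nn(fwd, thermo); tr <- tm_nn(rev, thermo)
  flags <- character(0)
  if (tf <= 50) flags <- c(flags, "TM_LOW_FWD")
  if (tr <= 50) flags <- c(flags, "TM_LOW_REV")
  if (abs(tf - tr) >= 3) flags <- c(flags, "TM_IMBALANCE")
  flags
}
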