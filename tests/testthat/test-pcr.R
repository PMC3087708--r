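.genome_of <- function(...) {
  x <- c(...)
  g <- Biostrings::DNAStringSet(unname(x))
  names(g) <- names(x)
  g
}

test_that("a primer matching a unique substring gives exactly one site", {
  set.seed(101)
  chr <- o_rand_dna(3000, at = 0.5)
  primer <- substr(chr, 1001, 1022)
  sites <- find_binding_sites(primer, .genome_of(c(c1 = chr)))
  perfect <- sites[sites$matched_bases == nchar(primer), ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(perfect$strand, "+")
  expect_equal(perfect$start, 1000L)
  expect_equal(perfect$end, 1022L)
  # and on the minus strand via its reverse complement
  sites2 <- find_binding_sites(reverse_complement(primer),
                               .genome_of(c(c1 = chr)))
  perfect2 <- sites2[sites2$matched_bases == nchar(primer), ]
  expect_equal(perfect2$strand, "-")
  expect_equal(perfect2$start, 1000L)
})

test_that("a primer whose 3' tetramer is absent finds nothing", {
  chr <- paste(rep("AT", 500), collapse = "")
  primer <- "ATATATATATATATATGGGG"   # GGGG never occurs in an (AT)n genome
  expect_equal(nrow(find_binding_sites(primer, .genome_of(c(c1 = chr)))), 0L)
})

test_that("one 5' mismatch is tolerated and counted", {
  set.seed(102)
  chr <- o_rand_dna(2000, at = 0.5)
  tpl <- substr(chr, 501, 524)
  primer <- tpl
  b <- substr(primer, 1, 1)
  substr(primer, 1, 1) <- setdiff(c("A", "C", "G", "T"), b)[1]
  sites <- find_binding_sites(primer, .genome_of(c(c1 = chr)))
  hit <- sites[sites$start == 500L & sites$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$matched_bases, nchar(primer) - 1L)
})

test_that("amplicon enumeration obeys size, uniqueness and max-length rules", {
  set.seed(103)
  chr <- o_rand_dna(3000, at = 0.5)
  fwd <- substr(chr, 299, 320)
  rev <- o_revcomp(substr(chr, 781, 802))
  amp <- enumerate_amplicons(fwd, rev, .genome_of(c(c1 = chr)))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$size, 504L)
  expect_equal(amp$start, 298L)
  expect_equal(amp$end, 802L)
  expect_equal(amp$ppc, 1)
  expect_equal(amplicon_sequences(amp, .genome_of(c(c1 = chr))),
               substr(chr, 299, 802))

  # two fwd sites and two rev sites arranged to give exactly two short
  # pairings (cross pairings exceed the size cap)
  set.seed(104)
  left <- o_rand_dna(500); mid <- o_rand_dna(11000); right <- o_rand_dna(500)
  insert <- substr(chr, 299, 802)
  chr2 <- paste0(left, insert, mid, insert, right)
  amp2 <- enumerate_amplicons(fwd, rev, .genome_of(c(c1 = chr2)))
  expect_equal(nrow(amp2), 2L)
  expect_equal(amp2$size, c(504L, 504L))

  # a valid pairing at 12 kb is excluded by the default cap, kept if raised
  chr3 <- paste0(substr(chr, 299, 320), o_rand_dna(11656),
                 substr(chr, 781, 802))
  expect_equal(nrow(enumerate_amplicons(fwd, rev, .genome_of(c(c1 = chr3)))),
               0L)
  expect_equal(enumerate_amplicons(fwd, rev, .genome_of(c(c1 = chr3)),
                                   max_amplicon_bp = 15000)$size, 11700L)
})

test_that("site and amplicon sets equal the exhaustive-scan oracle", {
  set.seed(105)
  for (draw in 1:30) {
    chrom <- o_rand_dna(1200)
    # half the draws plant a mutated copy of a genuine window to exercise
    # mismatched sites; the rest use random primers
    if (draw %% 2 == 0) {
      at <- sample(900, 1)
      primer <- substr(chrom, at, at + 19)
      k <- sample(16, 1)
      substr(primer, k, k) <-
        sample(setdiff(c("A", "C", "G", "T"), substr(primer, k, k)), 1)
    } else {
      primer <- o_rand_dna(20, at = 0.5)
    }
    got <- find_binding_sites(primer, .genome_of(c(z = chrom)))
    want <- oracle_sites(primer, "z", chrom)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      got <- got[order(got$strand, got$start), ]
      want <- want[order(want$strand, want$start), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[c("strand", "start", "end", "matched_bases")],
                   want[c("strand", "start", "end", "matched_bases")])
      expect_equal(got$duplex_tm, want$duplex_tm, tolerance = 1e-9)
    }
  }
})

test_that("raising the Tm or ppc threshold never adds amplicons", {
  set.seed(106)
  chrom <- o_rand_dna(4000, at = 0.5)
  fwd <- substr(chrom, 101, 122)
  rev <- o_revcomp(substr(chrom, 899, 920))
  g <- .genome_of(c(c1 = chrom))
  key <- function(a) paste(a$chrom, a$start, a$end)
  base <- enumerate_amplicons(fwd, rev, g, min_duplex_tm = 40,
                              ppc_cutoff = 0.2)
  for (tm in c(45, 50, 55, 60))
    expect_true(all(key(enumerate_amplicons(fwd, rev, g,
                                            min_duplex_tm = tm)) %in%
                    key(base)))
  for (pc in c(0.3, 0.6, 0.9))
    expect_true(all(key(enumerate_amplicons(fwd, rev, g, ppc_cutoff = pc,
                                            min_duplex_tm = 40)) %in%
                    key(base)))
})

test_that("primer-pair flags encode the efficiency criteria", {
  # AT-only primers melt far below 50; a GC-rich 22-mer far above
  low <- "ATTATAATAATATTAT"
  high <- "GCGGCTAGGCATCGGCACGGTC"
  expect_lt(tm_nn(low), 50)
  expect_gt(tm_nn(high), 50)
  expect_setequal(primer_pair_flags(low, high),
                  c("TM_LOW_FWD", "TM_IMBALANCE"))
  expect_setequal(primer_pair_flags(high, low),
                  c("TM_LOW_REV", "TM_IMBALANCE"))
  # balanced pair within 3 degrees carries no flags
  set.seed(107)
  repeat {
    a <- o_rand_dna(20, at = 0.5); b <- o_rand_dna(20, at = 0.5)
    if (tm_nn(a) > 52 && tm_nn(b) > 52 && abs(tm_nn(a) - tm_nn(b)) < 2.5)
      break
  }
  expect_length(primer_pair_flags(a, b), 0L)
})
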