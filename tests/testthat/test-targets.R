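.tiny_genes <- function() {
  data.frame(gene_id = c("gA", "gB", "gRet"),
             chrom = c("c1", "c1", "c2"),
             start = c(100L, 600L, 50L), end = c(500L, 900L, 400L),
             strand = c("+", "-", "+"),
             status = c("ALIVE", "ALIVE", "RETIRED"),
             successor = c(NA, NA, "gA"), stringsAsFactors = FALSE)
}

test_that("gene liveness lookup distinguishes alive/retired/unknown", {
  g <- .tiny_genes()
  expect_equal(check_gene_alive("gA", g), "ALIVE")
  expect_equal(check_gene_alive("gRet", g), "RETIRED")
  expect_equal(check_gene_alive("nope", g), "UNKNOWN")
})

test_that("positional overlap reports genes, multi-gene spans, intergenic", {
  g <- .tiny_genes()
  expect_equal(genes_overlapping("c1", 150, 350, g), "gA")
  expect_setequal(genes_overlapping("c1", 450, 700, g), c("gA", "gB"))
  expect_equal(genes_overlapping("c1", 510, 590, g), "INTERGENIC")
  # half-open convention: an amplicon ending exactly at a gene start does
  # not overlap it
  expect_equal(genes_overlapping("c1", 520, 600, g), "INTERGENIC")
  expect_equal(genes_overlapping("c1", 520, 601, g), "gB")
  expect_error(genes_overlapping("c9", 0, 10, g), "unknown chromosome")
})

test_that("similarity score is 100 only for identity and tracks the DP oracle", {
  set.seed(31)
  s <- o_rand_dna(500)
  expect_equal(similarity_score(c(s, s)), 100)

  # 300-mer with exactly 15 substitutions: ungapped optimum, identity 95
  a <- o_rand_dna(300)
  b <- a
  pos <- sample(300, 15)
  for (p in pos)
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(a, p, p)), 1)
  expect_equal(similarity_score(c(a, b)), 95)
  expect_equal(oracle_nw_identity(a, b), 95)

  # unrelated random sequences score far below the homolog threshold
  u <- o_rand_dna(300); v <- o_rand_dna(300)
  expect_lt(similarity_score(c(u, v)), 80)
  expect_lt(oracle_nw_identity(u, v), 80)

  # permutation invariance over three sequences
  tri <- c(a, b, o_rand_dna(300))
  expect_equal(similarity_score(tri), similarity_score(rev(tri)))

  expect_error(similarity_score("ACGT"), "at least 2")
  expect_error(similarity_score(c("ACGT", "ACGT")), "at least 50")
})

test_that("similarity agrees with the DP oracle on gapped variants", {
  set.seed(32)
  for (i in 1:5) {
    a <- o_rand_dna(120)
    # delete a short block to force a gapped alignment
    cut <- sample(40:70, 1)
    b <- paste0(substr(a, 1, cut), substr(a, cut + sample(3:6, 1), 120))
    expect_equal(similarity_score(c(a, b)), oracle_nw_identity(a, b),
                 tolerance = 0.75)
  }
})

test_that("target search finds verbatim and diverged gene copies", {
  set.seed(33)
  fx <- small_genome_fixture()
  idx <- build_gene_index(fx$genes, fx$genome)
  gi <- which(fx$genes$status == "ALIVE")[1]
  gene_seq <- as.character(Biostrings::subseq(
    fx$genome[[fx$genes$chrom[gi]]], fx$genes$start[gi] + 1,
    fx$genes$end[gi]))

  # amplicon copied verbatim from inside the gene: full-identity hit
  amp <- substr(gene_seq, 30, 329)
  hits <- find_target_genes(amp, idx)
  expect_true(fx$genes$gene_id[gi] %in% hits$gene_id)
  top <- hits[hits$gene_id == fx$genes$gene_id[gi], ]
  expect_equal(top$identity, 1)
  expect_equal(top$aligned_length, 300L)

  # 250 nt amplicon mutated to ~85% identity is still reported
  amp2 <- substr(gene_seq, 30, 279)
  b <- strsplit(amp2, "")[[1]]
  pos <- sample(250, 37)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  amp2 <- paste(b, collapse = "")
  hits2 <- find_target_genes(amp2, idx)
  expect_true(fx$genes$gene_id[gi] %in% hits2$gene_id)
  expect_gt(hits2$identity[hits2$gene_id == fx$genes$gene_id[gi]], 0.80)

  # the same divergence over only 150 nt fails the length rule
  amp3 <- substr(amp2, 1, 150)
  hits3 <- find_target_genes(amp3, idx)
  expect_equal(nrow(hits3), 0L)
  expect_true(attr(hits3, "short_amplicon"))
  # a 250 nt amplicon with no qualifying window also returns nothing,
  # without the short-amplicon flag
  hits4 <- find_target_genes(o_rand_dna(250), idx)
  expect_equal(nrow(hits4), 0L)
  expect_false(attr(hits4, "short_amplicon"))
})

test_that("target hit set equals the exhaustive window oracle", {
  set.seed(34)
  fx <- small_genome_fixture(seed = 35)
  idx <- build_gene_index(fx$genes, fx$genome)
  gene_seqs <- vapply(seq_len(nrow(fx$genes)), function(i) {
    as.character(Biostrings::subseq(fx$genome[[fx$genes$chrom[i]]],
                                    fx$genes$start[i] + 1, fx$genes$end[i]))
  }, character(1))
  for (rep in 1:8) {
    gi <- sample(nrow(fx$genes), 1)
    glen <- nchar(gene_seqs[gi])
    size <- sample(210:min(400, glen - 10), 1)
    at <- sample(glen - size, 1)
    amp <- substr(gene_seqs[gi], at, at + size - 1)
    # mutate near the threshold so both outcomes occur across draws
    rate <- sample(c(0.05, 0.15, 0.22), 1)
    b <- strsplit(amp, "")[[1]]
    pos <- which(stats::runif(length(b)) < rate)
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    amp <- paste(b, collapse = "")
    got <- find_target_genes(amp, idx)$gene_id
    want <- fx$genes$gene_id[vapply(gene_seqs, oracle_has_hit_fast, logical(1),
                                    amp = amp)]
    expect_setequal(got, want)
  }
})

.shift_library <- function() {
  data.frame(
    clone_name = c("F36H12.3", "F36H12.17", "B0554.1", "Y39D8A.1",
                   "F32B5.4", "C45E1.1", "other"),
    annotated_gene = c("F36H12.3", "F36H12.17", "B0554.1", "Y39D8A.1",
                       "F32B5.4", "C45E1.1", "other"),
    location = c("IV-2B04", "IV-2D04", "V-1K09", "V-1K07",
                 "I-1I14", "I-1M14", "II-1A01"),
    stringsAsFactors = FALSE) |>
    (\(d) cbind(d, parse_plate_location(d$location)))()
}

test_that("loading-shift forensics recovers row and column offsets", {
  lib <- .shift_library()
  # vertical two-row shift in the same column of the same plate
  s <- detect_loading_shift(lib[1, ], "F36H12.17", lib)
  expect_equal(s$axis, "ROW"); expect_equal(s$offset, 2L)
  expect_true(s$same_plate)
  # horizontal two-column shift in the same row
  s <- detect_loading_shift(lib[3, ], "Y39D8A.1", lib)
  expect_equal(s$axis, "COLUMN"); expect_equal(s$offset, -2L)
  # vertical four-row shift
  s <- detect_loading_shift(lib[5, ], "C45E1.1", lib)
  expect_equal(s$axis, "ROW"); expect_equal(s$offset, 4L)
  # no shift when the sequenced gene is the annotated one, or off-plate
  expect_null(detect_loading_shift(lib[1, ], "F36H12.3", lib))
  expect_null(detect_loading_shift(lib[1, ], "other", lib))
  expect_null(detect_loading_shift(lib[1, ], "absent", lib))
})
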