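test_that("genome generation is deterministic and honors its contract", {
  a <- small_genome_fixture(seed = 51)
  b <- small_genome_fixture(seed = 51)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  c <- small_genome_fixture(seed = 52)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))

  g <- a$genes
  expect_true(all(g$start >= 0 & g$start < g$end))
  for (i in seq_len(nrow(g)))
    expect_lte(g$end[i], Biostrings::width(a$genome[g$chrom[i]]))
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_equal(sum(g$status == "RETIRED"), 2L)
  succ <- g$successor[g$status == "RETIRED"]
  expect_true(all(succ %in% g$gene_id[g$status == "ALIVE"]))
  # retired genes and their successors sit at different loci
  for (r in which(g$status == "RETIRED")) {
    s <- match(g$successor[r], g$gene_id)
    expect_true(g$chrom[r] != g$chrom[s] || g$start[r] != g$start[s])
  }
})

test_that("embedded paralog pairs reach the homolog similarity threshold", {
  fx <- generate_genome(n_chrom = 3, genes_per_chrom = 6,
                        n_paralog_pairs = 3, paralog_identity = 0.96,
                        n_retired = 0, seed = 53)
  pp <- attr(fx$genes, "paralog_pairs")
  expect_equal(nrow(pp), 3L)
  for (k in seq_len(nrow(pp))) {
    i <- match(pp$gene1[k], fx$genes$gene_id)
    j <- match(pp$gene2[k], fx$genes$gene_id)
    expect_true(fx$genes$chrom[i] != fx$genes$chrom[j])
    s1 <- as.character(Biostrings::subseq(fx$genome[[fx$genes$chrom[i]]],
                                          fx$genes$start[i] + 1,
                                          fx$genes$end[i]))
    s2 <- as.character(Biostrings::subseq(fx$genome[[fx$genes$chrom[j]]],
                                          fx$genes$start[j] + 1,
                                          fx$genes$end[j]))
    expect_gte(similarity_score(c(s1, s2)), 95)
    expect_gte(oracle_nw_identity(substr(s1, 1, 150), substr(s2, 1, 150)),
               90)
  }
})

test_that("degenerate genome requests behave sensibly", {
  fx <- generate_genome(n_chrom = 1, genes_per_chrom = 0,
                        n_paralog_pairs = 0, n_retired = 0, seed = 54)
  expect_equal(nrow(fx$genes), 0L)
  expect_gt(Biostrings::width(fx$genome)[1], 0L)
  expect_error(generate_genome(n_chrom = 1, genes_per_chrom = 2,
                               n_paralog_pairs = 2, n_retired = 0),
               "infeasible")
  expect_error(generate_genome(paralog_identity = 0.5), "paralog_identity")
  expect_error(defect_spec(nonspecific_primers = 0.9,
                           intergenic_amplicon = 0.3), "sum")
})

test_that("library generation injects the requested defects with truth", {
  fx <- small_genome_fixture(seed = 55)
  lib <- generate_library(
    fx$genome, fx$genes, n_clones = 12,
    defects = defect_spec(nonspecific_primers = 1 / 12,
                          intergenic_amplicon = 1 / 12,
                          retired_remapped = 1 / 12,
                          loading_shift = 1 / 12, empty_vector = 1 / 12,
                          homolog_comigration = 1 / 12,
                          loading_shift_patterns = list(
                            list(axis = "COLUMN", offset = 2L))),
    seed = 55)
  expect_equal(nrow(lib$clones), 12L)
  expect_equal(sort(unique(lib$truth$class)),
               sort(c("SPECIFIC", "NONSPECIFIC_PRIMERS",
                      "INTERGENIC_AMPLICON", "RETIRED_REMAPPED",
                      "LOADING_SHIFT", "EMPTY_VECTOR",
                      "HOMOLOG_COMIGRATION")))
  # determinism of the full bundle
  lib2 <- generate_library(
    fx$genome, fx$genes, n_clones = 12,
    defects = defect_spec(1 / 12, 1 / 12, 1 / 12, 1 / 12, 1 / 12, 1 / 12,
                          loading_shift_patterns = list(
                            list(axis = "COLUMN", offset = 2L))),
    seed = 55)
  expect_identical(lib$clones, lib2$clones)
  expect_identical(lib$truth, lib2$truth)
  expect_identical(as.character(lib$genome), as.character(lib2$genome))

  # the retired clone is annotated to a RETIRED id whose successor it
  # actually amplifies
  rt <- lib$truth[lib$truth$class == "RETIRED_REMAPPED", ]
  expect_equal(check_gene_alive(rt$clone_name, fx$genes), "RETIRED")
  expect_equal(fx$genes$successor[match(rt$clone_name, fx$genes$gene_id)],
               rt$actual_gene)
  # the shift clone's partner really is one well pair away
  sh <- lib$truth[lib$truth$class == "LOADING_SHIFT", ]
  ci <- match(sh$clone_name, lib$clones$clone_name)
  pj <- match(sh$partner_clone, lib$clones$clone_name)
  expect_equal(lib$clones$row_i[pj], lib$clones$row_i[ci])
  expect_equal(lib$clones$col[pj] - lib$clones$col[ci], 2L)
  # the empty-vector clone has no binding site at all
  ev <- lib$clones[lib$truth$class == "EMPTY_VECTOR", ]
  expect_equal(nrow(enumerate_amplicons(ev$fwd, ev$rev, lib$genome)), 0L)
})

test_that("sequencing simulation maps truth and perturbs at the stated rate", {
  truth <- data.frame(
    clone_name = sprintf("c%03d", 1:500),
    class = rep(c("SPECIFIC", "RETIRED_REMAPPED", "LOADING_SHIFT",
                  "EMPTY_VECTOR", "NONSPECIFIC_PRIMERS"), 100),
    actual_gene = NA_character_, shift_axis = NA_character_,
    shift_offset = NA_integer_, partner_clone = NA_character_,
    stringsAsFactors = FALSE)
  clones <- data.frame(clone_name = truth$clone_name)

  v0 <- simulate_sequencing(clones, truth, misread_rate = 0, seed = 61)
  expect_equal(unique(v0$outcome[truth$class == "SPECIFIC"]), "RELIABLE")
  expect_equal(unique(v0$outcome[truth$class == "RETIRED_REMAPPED"]),
               "REMAPPED_RETIRED")
  expect_equal(unique(v0$outcome[truth$class == "LOADING_SHIFT"]),
               "REMAPPED_WRONG_INSERT")
  expect_equal(unique(v0$outcome[truth$class == "EMPTY_VECTOR"]),
               "UNRELIABLE")

  # misreads follow the binomial within 3 sigma (n = 500, p = 0.1)
  v1 <- simulate_sequencing(clones, truth, misread_rate = 0.1, seed = 61)
  flips <- sum(v1$outcome != v0$outcome)
  expect_gt(flips, 50 - 3 * sqrt(500 * 0.1 * 0.9))
  expect_lt(flips, 50 + 3 * sqrt(500 * 0.1 * 0.9))
  # determinism per seed
  expect_identical(v1, simulate_sequencing(clones, truth, 0.1, seed = 61))

  empty <- simulate_sequencing(clones[0, , drop = FALSE], truth[0, ], 0, 1)
  expect_equal(nrow(empty), 0L)
  expect_error(simulate_sequencing(clones, truth, misread_rate = 1), "rate")
})

test_that("plate labels do not influence scores, only locations", {
  fx <- small_genome_fixture(seed = 56)
  d <- defect_spec(0, 0, 0, 0, 0, 0)
  l1 <- generate_library(fx$genome, fx$genes, 6, d,
                         plate_labels = c("I", "II"), seed = 57)
  l2 <- generate_library(fx$genome, fx$genes, 6, d,
                         plate_labels = c("QQ"), seed = 57)
  expect_identical(l1$clones[c("fwd", "rev", "annotated_gene")],
                   l2$clones[c("fwd", "rev", "annotated_gene")])
  e1 <- evaluate_library(l1$clones, l1$genome, fx$genes)
  e2 <- evaluate_library(l2$clones, l2$genome, fx$genes)
  expect_identical(e1$score, e2$score)
  expect_identical(e1$category, e2$category)
})
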