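# End-to-end clone evaluation: in-silico PCR -> virtual gel -> similarity
# penalties -> target mapping -> score, category and flags.

#' Evaluate a single clone
#'
#' Runs the full reliability procedure for one primer pair: 3'-end free
#' energy check, amplicon enumeration, co-migration grouping with similarity
#' penalties, penalty-ledger scoring, target-gene mapping and flag
#' assignment.  Clones whose amplicons hit no gene at all cannot be trusted
#' to silence their annotated target, so a nominally green score is
#' downgraded to the yellow (marginal) category, matching the yellow "R"
#' plate marking for such clones.
#'
#' @param clone A single-row clone record.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param genes A gene table.
#' @param index Optional prebuilt [build_gene_index()] for `genes`.
#' @param thermo A [thermo_params()].
#' @param gel A [gel_config()].
#' @param max_amplicon_bp,ppc_cutoff,min_duplex_tm,word_size In-silico PCR
#'   settings (see [enumerate_amplicons()]).
#' @param min_identity,min_len Target-search thresholds (see
#'   [find_target_genes()]).
#' @return A list: `clone_name, score, category, flags, predicted_targets`
#'   (data.frame of hits), `overlap_genes`, `amplicons`, `ledger`,
#'   `annotated_status`.
#' @export
evaluate_clone <- function(clone, genome, genes, index = NULL,
                           thermo = thermo_params(), gel = gel_config(),
                           max_amplicon_bp = 10000, ppc_cutoff = 0.3,
                           min_duplex_tm = 50, word_size = 4,
                           min_identity = 0.80, min_len = 200) {
  if (is.null(index)) index <- build_gene_index(genes, genome)
  dg_f <- dg_3prime_end(clone$fwd, thermo)
  dg_r <- dg_3prime_end(clone$rev, thermo)
  tmf <- primer_pair_flags(clone$fwd, clone$rev, thermo)
  amp <- enumerate_amplicons(clone$fwd, clone$rev, genome,
                             max_amplicon_bp = max_amplicon_bp,
                             ppc_cutoff = ppc_cutoff,
                             min_duplex_tm = min_duplex_tm,
                             word_size = word_size, thermo = thermo)
  seqs <- if (nrow(amp) > 0) amplicon_sequences(amp, genome) else character(0)

  group_sims <- numeric(0)
  if (nrow(amp) >= 2L) {
    grp <- comigrating_groups(amp$size, gel)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) >= 2L)
        group_sims <- c(group_sims, similarity_score(seqs[idx]))
    }
  }
  ledger <- score_clone(dg_f, dg_r, nrow(amp), group_sims)

  hits <- data.frame(gene_id = character(0), identity = numeric(0),
                     aligned_length = integer(0), stringsAsFactors = FALSE)
  overlap <- character(0)
  short_amp <- FALSE
  for (i in seq_len(nrow(amp))) {
    h <- find_target_genes(seqs[i], index, min_identity = min_identity,
                           min_len = min_len)
    short_amp <- short_amp || isTRUE(attr(h, "short_amplicon"))
    hits <- rbind(hits, h)
    overlap <- union(overlap,
                     genes_overlapping(amp$chrom[i], amp$start[i],
                                       amp$end[i], genes))
  }
  if (nrow(hits) > 0) {
    hits <- hits[order(-hits$identity), ]
    hits <- hits[!duplicated(hits$gene_id), ]
    rownames(hits) <- NULL
  }

  flags <- tmf
  if (nrow(amp) > 0)
    flags <- c(flags, remap_flags(clone$annotated_gene, hits$gene_id))
  if (short_amp) flags <- c(flags, "SHORT_AMPLICON")

  category <- classify(ledger$final_score)
  if ("NO_TARGET" %in% flags && category == "RELIABLE")
    category <- "MARGINAL"

  list(clone_name = clone$clone_name, score = ledger$final_score,
       category = category, flags = sort(unique(flags)),
       predicted_targets = hits, overlap_genes = overlap,
       amplicons = amp, ledger = ledger,
       annotated_status = check_gene_alive(clone$annotated_gene, genes))
}

#' Evaluate a whole clone library
#'
#' @param clones A clone table from [read_clone_table()] or
#'   [generate_library()].
#' @inheritParams evaluate_clone
#' @param verbose Print one progress line per 50 clones to stderr.
#' @return A data.frame with one row per clone (`clone_name, location,
#'   chrom_label, plate_no, row, row_i, col, annotated_gene,
#'   annotated_status, score, category, flags, predicted_targets,
#'   n_amplicons`); per-clone detail objects (ledger, amplicon table, hit
#'   table) are in `attr(, "details")`, named by clone.
#' @export
evaluate_library <- function(clones, genome, genes, thermo = thermo_params(),
                             gel = gel_config(), max_amplicon_bp = 10000,
                             ppc_cutoff = 0.3, min_duplex_tm = 50,
                             word_size = 4, min_identity = 0.80,
                             min_len = 200, verbose = FALSE) {
  index <- build_gene_index(genes, genome)
  details <- vector("list", nrow(clones))
  rows <- vector("list", nrow(clones))
  for (i in seq_len(nrow(clones))) {
    ev <- evaluate_clone(clones[i, ], genome, genes, index, thermo, gel,
                         max_amplicon_bp, ppc_cutoff, min_duplex_tm,
                         word_size, min_identity, min_len)
    details[[i]] <- ev
    rows[[i]] <- data.frame(
      clone_name = ev$clone_name, location = clones$location[i],
      chrom_label = clones$chrom_label[i], plate_no = clones$plate_no[i],
      row = clones$row[i], row_i = clones$row_i[i], col = clones$col[i],
      annotated_gene = clones$annotated_gene[i],
      annotated_status = ev$annotated_status,
      score = ev$score, category = ev$category,
      flags = paste(ev$flags, collapse = ","),
      predicted_targets = paste(ev$predicted_targets$gene_id,
                                collapse = ","),
      n_amplicons = nrow(ev$amplicons), stringsAsFactors = FALSE)
    if (verbose && i %% 50L == 0L)
      message("evaluated ", i, "/", nrow(clones), " clones")
  }
  out <- do.call(rbind, rows)
  names(details) <- out$clone_name
  attr(out, "details") <- details
  out
}
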