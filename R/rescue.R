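# Replacement-primer design for marginal/unreliable clones: up to five
# alternative pairs per gene, each guaranteed to pass the package's own
# screen (single genome-wide amplicon mapping back to the gene).

#' Design alternative primer pairs for a gene
#'
#' Slides candidate amplicon windows across the gene body, keeps pairs whose
#' primers fall in `tm_range` with a Tm difference below 3 degrees and a
#' 3'-pentamer free energy no more stable than -9 kcal/mol, and verifies
#' each survivor with the in-silico PCR engine: it must yield exactly one
#' genome-wide amplicon whose similarity search maps to this gene and no
#' other.  Candidates are ranked by Tm balance, then by product size closest
#' to 1 kb.
#'
#' @param gene_id An ALIVE gene of length >= 300 nt.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param genes A gene table.
#' @param n Maximum number of pairs returned (default 5).
#' @param len_range Primer length range (default 18-25).
#' @param tm_range Primer Tm range in Celsius (default 55-65).
#' @param thermo A [thermo_params()].
#' @return A data.frame of up to `n` rows: `fwd, rev, size, tm_fwd, tm_rev,
#'   start, end` (amplicon interval, 0-based half-open).
#' @export
design_alternatives <- function(gene_id, genome, genes, n = 5,
                                len_range = c(18, 25), tm_range = c(55, 65),
                                thermo = thermo_params()) {
  gi <- match(gene_id, genes$gene_id)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  if (genes$status[gi] == "RETIRED")
    stop("gene ", gene_id, " is retired; remap the clone instead")
  glen <- genes$end[gi] - genes$start[gi]
  if (glen < 300) stop("gene ", gene_id, " is shorter than 300 nt")
  chrom <- genes$chrom[gi]
  template <- as.character(genome[[chrom]])
  lens <- seq(len_range[1], len_range[2])

  sizes <- seq(240L, min(glen - 40L, 2000L), by = 40L)
  offsets <- seq(10L, glen - 40L, by = 25L)
  cand <- list()
  for (size in sizes) for (off in offsets) {
    if (off + size > glen - 10L) next
    w0 <- genes$start[gi] + off
    f <- .tune_fwd(template, w0 + 1L, thermo, lens,
                   lo = tm_range[1], hi = tm_range[2])
    if (is.null(f)) next
    r <- .tune_rev(template, w0 + size, thermo, lens,
                   lo = max(tm_range[1], f$tm - 2.99),
                   hi = min(tm_range[2], f$tm + 2.99))
    if (is.null(r)) next
    if (dg_3prime_end(f$seq, thermo) < -9 ||
        dg_3prime_end(r$seq, thermo) < -9) next
    cand[[length(cand) + 1L]] <- data.frame(
      fwd = f$seq, rev = r$seq, size = size, tm_fwd = f$tm, tm_rev = r$tm,
      start = w0, end = w0 + size, stringsAsFactors = FALSE)
  }
  if (length(cand) == 0L) return(.empty_rescue())
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(paste(cand$fwd, cand$rev)), ]
  cand <- cand[order(abs(cand$tm_fwd - cand$tm_rev),
                     abs(cand$size - 1000L)), ]

  index <- build_gene_index(genes, genome)
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    amp <- enumerate_amplicons(cand$fwd[i], cand$rev[i], genome,
                               thermo = thermo)
    if (nrow(amp) != 1L) next
    hits <- find_target_genes(amplicon_sequences(amp, genome), index)
    if (nrow(hits) != 1L || hits$gene_id != gene_id) next
    keep <- c(keep, i)
    if (length(keep) >= n) break
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_rescue <- function() {
  data.frame(fwd = character(0), rev = character(0), size = integer(0),
             tm_fwd = numeric(0), tm_rev = numeric(0), start = integer(0),
             end = integer(0), stringsAsFactors = FALSE)
}
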