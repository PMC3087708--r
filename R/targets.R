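# Deciding what each amplicon actually silences: positional overlap with the
# gene table, a 0-100 amplicon similarity score (mean pairwise global
# alignment identity), a seed-and-extend similarity search against unspliced
# gene sequences, retired-gene checks, and plate loading-shift forensics.

#' Look up whether a gene identifier is still alive
#'
#' @param gene_id Gene identifier.
#' @param genes A gene table from [read_gene_table()] or
#'   [generate_genome()].
#' @return `"ALIVE"`, `"RETIRED"`, or `"UNKNOWN"` when the id is absent.
#' @export
check_gene_alive <- function(gene_id, genes) {
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) "UNKNOWN" else genes$status[i]
}

#' Genes overlapping an amplicon interval
#'
#' @param chrom Chromosome id of the amplicon.
#' @param start,end Amplicon interval, 0-based half-open.
#' @param genes A gene table.
#' @return Character vector of overlapping gene ids, or the sentinel
#'   `"INTERGENIC"` when the interval touches no gene.
#' @export
genes_overlapping <- function(chrom, start, end, genes) {
  if (!chrom %in% genes$chrom)
    stop("unknown chromosome: ", chrom)
  g <- genes[genes$chrom == chrom, ]
  hit <- IRanges::overlapsAny(
    IRanges::IRanges(start = g$start + 1L, end = g$end),
    IRanges::IRanges(start = start + 1L, end = end))
  if (!any(hit)) "INTERGENIC" else g$gene_id[hit]
}

#' Similarity score of a set of amplicon sequences
#'
#' Scores sequence similarity on a 0-100 scale as 100 times the mean pairwise
#' identity over global (Needleman-Wunsch) alignments with match +1,
#' mismatch -1 and a linear gap penalty of -2 per gapped position; identity
#' of one alignment is matched positions over alignment length.  The score is
#' 100 exactly when all sequences are identical.  Co-migrating amplicon
#' groups scoring above 95 are treated as likely homologs.
#'
#' @param sequences Character vector of >= 2 DNA sequences, each >= 50 nt.
#' @param match,mismatch,gap Alignment scoring parameters.
#' @return Similarity score in `[0, 100]`.
#' @export
similarity_score <- function(sequences, match = 1, mismatch = -1, gap = -2) {
  if (length(sequences) < 2L)
    stop("similarity_score needs at least 2 sequences")
  if (any(nchar(sequences) < 50L))
    stop("each sequence must be at least 50 nt")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pids <- c()
  n <- length(sequences)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (sequences[i] == sequences[j]) { pids <- c(pids, 100); next }
    aln <- Biostrings::pairwiseAlignment(sequences[i], sequences[j],
                                         type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 0, gapExtension = -gap)
    pids <- c(pids, Biostrings::pid(aln, type = "PID1"))
  }
  mean(pids)
}

# ---- seed-and-extend target search ------------------------------------------

.gene_kmers <- function(seqs, k) {
  # returns, per sequence, its k-mer strings and 1-based positions
  lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(list(kmer = character(0), pos = integer(0)))
    pos <- seq_len(L - k + 1L)
    list(kmer = substring(s, pos, pos + k - 1L), pos = pos)
  })
}

#' Build a reusable seed index over unspliced gene sequences
#'
#' Extracts each gene's unspliced (genomic) sequence on both strands and
#' indexes its exact `seed_len`-mers.  Build once, pass to
#' [find_target_genes()] when scoring many amplicons against the same gene
#' table.
#'
#' @param genes A gene table.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param seed_len Exact-seed length (default 11, the classic BLASTN word
#'   size).
#' @return An opaque index object.
#' @export
build_gene_index <- function(genes, genome, seed_len = 11) {
  plus <- vapply(seq_len(nrow(genes)), function(i) {
    as.character(Biostrings::subseq(genome[[genes$chrom[i]]],
                                    start = genes$start[i] + 1L,
                                    end = genes$end[i]))
  }, character(1))
  minus <- reverse_complement(plus)
  seqs <- c(plus, minus)                 # 1..n plus, n+1..2n minus
  km <- .gene_kmers(seqs, seed_len)
  kmer <- unlist(lapply(km, `[[`, "kmer"), use.names = FALSE)
  pos <- unlist(lapply(km, `[[`, "pos"), use.names = FALSE)
  entry <- rep(seq_along(seqs), vapply(km, function(x) length(x$pos),
                                       integer(1)))
  ord <- order(kmer, method = "radix")
  kmer <- kmer[ord]; pos <- pos[ord]; entry <- entry[ord]
  starts <- c(1L, which(kmer[-1] != kmer[-length(kmer)]) + 1L)
  structure(list(
    gene_id = genes$gene_id, n = nrow(genes), seqs = seqs,
    seed_len = seed_len,
    keys = kmer[starts],
    run_start = starts, run_end = c(starts[-1] - 1L, length(kmer)),
    pos = pos, entry = entry), class = "gene_index")
}

# best window with identity > min_identity (strict, exact rational
# arithmetic) and length >= min_len along one diagonal; returns NULL or
# c(matches, len, margin)
.best_window <- function(m, min_identity, min_len) {
  L <- length(m)
  if (L < min_len) return(NULL)
  den <- 1000L
  num <- as.integer(round(min_identity * den))
  D <- c(0L, cumsum(den * as.integer(m) - num))   # D[k+1], k = 0..L
  best <- NULL; best_margin <- 0L
  min_d <- .Machine$integer.max; min_i <- 0L
  for (j in seq.int(min_len, L)) {
    cand <- D[j - min_len + 1L]
    if (cand < min_d) { min_d <- cand; min_i <- j - min_len }
    margin <- D[j + 1L] - min_d
    if (margin > best_margin) {
      best_margin <- margin
      best <- c(i = min_i, j = j)
    }
  }
  if (is.null(best)) return(NULL)
  seg <- seq.int(best[["i"]] + 1L, best[["j"]])
  c(matches = sum(m[seg]), len = length(seg), margin = best_margin)
}

.diag_match <- function(a, g, d) {
  # match vector of amplicon a against gene-strand sequence g on diagonal d
  # (gene position = amplicon position + d, both 1-based)
  La <- nchar(a); Lg <- nchar(g)
  i1 <- max(1L, 1L - d); i2 <- min(La, Lg - d)
  if (i2 - i1 + 1L < 1L) return(NULL)
  m <- charToRaw(substr(a, i1, i2)) == charToRaw(substr(g, i1 + d, i2 + d))
  m
}

#' Find genes a dsRNA amplicon could silence
#'
#' Seed-and-extend similarity search of an amplicon against every unspliced
#' gene sequence on both strands: exact `seed_len`-mer seeds define
#' candidate ungapped diagonals, and along each diagonal the maximal window
#' with identity above `min_identity` and length at least `min_len` is
#' sought.  Only hits passing both thresholds are reported, one (best) hit
#' per gene.  Amplicons shorter than `min_len` cannot qualify and return an
#' empty hit table flagged `SHORT_AMPLICON`.
#'
#' @param amplicon_sequence Amplicon sequence (plus strand).
#' @param index A [build_gene_index()] object (or pass `genes` + `genome`).
#' @param genes,genome Used to build a throwaway index when `index` is NULL.
#' @param min_identity Minimum identity fraction, exclusive (default 0.80).
#' @param min_len Minimum qualifying window length in nt (default 200).
#' @return A data.frame of hits `gene_id, identity, aligned_length`, sorted
#'   by decreasing identity; attribute `short_amplicon` is TRUE when the
#'   amplicon was below `min_len`.
#' @export
find_target_genes <- function(amplicon_sequence, index = NULL, genes = NULL,
                              genome = NULL, min_identity = 0.80,
                              min_len = 200) {
  if (is.null(index)) index <- build_gene_index(genes, genome)
  empty <- data.frame(gene_id = character(0), identity = numeric(0),
                      aligned_length = integer(0), stringsAsFactors = FALSE)
  a <- toupper(amplicon_sequence)
  if (nchar(a) < min_len) {
    attr(empty, "short_amplicon") <- TRUE
    return(empty)
  }
  k <- index$seed_len
  apos <- seq_len(nchar(a) - k + 1L)
  akmer <- substring(a, apos, apos + k - 1L)
  hit <- match(akmer, index$keys)
  ok <- !is.na(hit)
  if (!any(ok)) { attr(empty, "short_amplicon") <- FALSE; return(empty) }
  # candidate (entry, diagonal) pairs from all seed matches
  ent <- integer(0); dia <- integer(0)
  for (t in which(ok)) {
    r <- seq.int(index$run_start[hit[t]], index$run_end[hit[t]])
    ent <- c(ent, index$entry[r])
    dia <- c(dia, index$pos[r] - apos[t])
  }
  cand <- unique(data.frame(ent = ent, dia = dia))
  best <- list()
  for (r in seq_len(nrow(cand))) {
    e <- cand$ent[r]
    m <- .diag_match(a, index$seqs[e], cand$dia[r])
    if (is.null(m)) next
    w <- .best_window(m, min_identity, min_len)
    if (is.null(w)) next
    gidx <- if (e > index$n) e - index$n else e
    gid <- index$gene_id[gidx]
    if (is.null(best[[gid]]) || w[["margin"]] > best[[gid]][["margin"]])
      best[[gid]] <- w
  }
  if (length(best) == 0L) { attr(empty, "short_amplicon") <- FALSE; return(empty) }
  out <- data.frame(
    gene_id = names(best),
    identity = vapply(best, function(w) w[["matches"]] / w[["len"]],
                      numeric(1)),
    aligned_length = vapply(best, function(w) as.integer(w[["len"]]),
                            integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$identity, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "short_amplicon") <- FALSE
  out
}

# ---- plate loading-shift forensics ------------------------------------------

#' Detect a plate loading-error shift
#'
#' Given a clone whose sequenced product identifies gene `actual_gene`,
#' searches the library for the clone annotated to that gene.  If it sits on
#' the same plate in the same column, the mix-up is a vertical (ROW) shift;
#' in the same row, a horizontal (COLUMN) shift.  The signed offset is
#' (position of the actual gene's clone) minus (position of this clone), in
#' wells; ties between several candidate clones are broken by smallest
#' absolute offset.
#'
#' @param clone A single-row clone record (from [read_clone_table()]).
#' @param actual_gene Gene identified by sequencing.
#' @param clones The full clone table.
#' @return `NULL` when no same-plate row/column shift explains the mix-up,
#'   else a list with `axis` (`"ROW"`/`"COLUMN"`), `offset` (signed integer,
#'   non-zero), `same_plate = TRUE` and `partner_clone`.
#' @export
detect_loading_shift <- function(clone, actual_gene, clones) {
  if (is.na(actual_gene) || actual_gene == clone$annotated_gene) return(NULL)
  cand <- clones[clones$annotated_gene == actual_gene &
                 clones$clone_name != clone$clone_name, , drop = FALSE]
  cand <- cand[cand$chrom_label == clone$chrom_label &
               cand$plate_no == clone$plate_no, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  shifts <- list()
  for (i in seq_len(nrow(cand))) {
    if (cand$col[i] == clone$col && cand$row_i[i] != clone$row_i) {
      shifts[[length(shifts) + 1L]] <- list(
        axis = "ROW", offset = cand$row_i[i] - clone$row_i,
        same_plate = TRUE, partner_clone = cand$clone_name[i])
    } else if (cand$row_i[i] == clone$row_i && cand$col[i] != clone$col) {
      shifts[[length(shifts) + 1L]] <- list(
        axis = "COLUMN", offset = cand$col[i] - clone$col,
        same_plate = TRUE, partner_clone = cand$clone_name[i])
    }
  }
  if (length(shifts) == 0L) return(NULL)
  shifts[[which.min(vapply(shifts, function(s) abs(s$offset), numeric(1)))]]
}
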