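# Seeded generators for toy genomes, gene tables, plated clone libraries with
# injected defects, and simulated sequencing outcomes.  The generator designs
# every primer with the pipeline's own thermodynamic model, so injected
# defects are not trivially detectable through the intrinsic Tm flags, and it
# emits a ground-truth sidecar so tests never reverse-engineer intent from
# sequences.

.with_seed <- function(seed, code, salt = 0L) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  # salt decouples the streams of the different generators so that calling
  # them with the same user seed never replays overlapping draws
  set.seed(bitwXor(as.integer(seed), as.integer(salt)))
  force(code)
}

.rand_dna <- function(n, at = 0.56) {
  if (n <= 0) return("")
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# substitute an exact count of positions so the realized divergence equals
# the requested rate (binomial jitter would let pairs drift below the
# homolog similarity threshold they are meant to sit above)
.mutate_dna <- function(seq, rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- sample(length(b), round(rate * length(b)))
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

# pick a primer length whose perfect-duplex Tm lies in [lo, hi], closest to
# the midpoint, and whose 3' pentamer is not over-stable (any sane design
# tool rejects primers failing the dG rule); template is a plain character
# chromosome/gene string
.tune_fwd <- function(template, start1, thermo, lens = 18:25,
                      lo = 52.5, hi = 63) {
  best <- NULL
  for (L in lens) {
    s <- substr(template, start1, start1 + L - 1L)
    if (nchar(s) < L || grepl("[^ACGT]", s)) next
    tm <- tm_nn(s, thermo)
    if (tm < lo || tm > hi) next
    if (dg_3prime_end(s, thermo) < -9) next
    if (is.null(best) || abs(tm - 57.5) < abs(best$tm - 57.5))
      best <- list(seq = s, len = L, tm = tm)
  }
  best
}

.tune_rev <- function(template, end1, thermo, lens = 18:25,
                      lo = 52.5, hi = 63) {
  best <- NULL
  for (L in lens) {
    if (end1 - L + 1L < 1L) next
    s <- substr(template, end1 - L + 1L, end1)
    if (grepl("[^ACGT]", s)) next
    p <- reverse_complement(s)
    tm <- tm_nn(p, thermo)
    if (tm < lo || tm > hi) next
    if (dg_3prime_end(p, thermo) < -9) next
    if (is.null(best) || abs(tm - 57.5) < abs(best$tm - 57.5))
      best <- list(seq = p, len = L, tm = tm)
  }
  best
}

# design a balanced pair amplifying [w0+1 .. w0+size] (1-based) of `template`
.tune_pair <- function(template, w0, size, thermo, dtm_max = 2.8) {
  f <- .tune_fwd(template, w0 + 1L, thermo)
  if (is.null(f)) return(NULL)
  r <- .tune_rev(template, w0 + size, thermo,
                 lo = max(52.5, f$tm - dtm_max), hi = min(63, f$tm + dtm_max))
  if (is.null(r)) return(NULL)
  list(fwd = f$seq, rev = r$seq, size = size, w0 = w0,
       tm_fwd = f$tm, tm_rev = r$tm)
}

#' Defect mix for a synthetic clone library
#'
#' Fractions of each injected defect class; the remainder of the library is
#' `SPECIFIC` (clean clones).  Defaults reproduce the stress mix used for
#' parameter-recovery validation: 10% of each hard defect plus a small
#' homolog-co-migration fraction.
#'
#' @param nonspecific_primers Fraction of clones whose primers also amplify
#'   a co-migrating unrelated (intergenic) product.
#' @param intergenic_amplicon Fraction whose single amplicon lies in a gene
#'   desert.
#' @param retired_remapped Fraction annotated to a retired gene id while the
#'   primers amplify its successor gene.
#' @param loading_shift Fraction placed a fixed number of wells away from the
#'   well whose gene they actually amplify.
#' @param empty_vector Fraction whose primers bind nowhere.
#' @param homolog_comigration Fraction amplifying both members of a >95%
#'   paralog pair.
#' @param loading_shift_patterns List of `c(axis, offset)` pairs cycled over
#'   the shift clones (axis `"ROW"` or `"COLUMN"`, offset in wells).
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(nonspecific_primers = 0.10,
                        intergenic_amplicon = 0.10,
                        retired_remapped = 0.10,
                        loading_shift = 0.10,
                        empty_vector = 0.10,
                        homolog_comigration = 0.05,
                        loading_shift_patterns = list(
                          list(axis = "ROW", offset = 2L),
                          list(axis = "ROW", offset = 4L),
                          list(axis = "COLUMN", offset = -2L))) {
  fr <- c(NONSPECIFIC_PRIMERS = nonspecific_primers,
          INTERGENIC_AMPLICON = intergenic_amplicon,
          RETIRED_REMAPPED = retired_remapped,
          LOADING_SHIFT = loading_shift,
          EMPTY_VECTOR = empty_vector,
          HOMOLOG_COMIGRATION = homolog_comigration)
  if (any(fr < 0) || sum(fr) > 1)
    stop("defect fractions must be >= 0 and sum to <= 1")
  structure(list(fractions = fr,
                 loading_shift_patterns = loading_shift_patterns),
            class = "defect_spec")
}

#' Generate a toy genome with gene models, paralog families and retired names
#'
#' Builds `n_chrom` chromosomes of random (AT-biased) DNA carrying
#' non-overlapping genes separated by intergenic spans, plus two long gene
#' deserts per chromosome.  `n_paralog_pairs` gene pairs are embedded on
#' *different* chromosomes at the requested sequence identity, sharing exact
#' primer-window copies so a single primer pair can amplify both members.
#' `n_retired` genes carry retired-style identifiers, RETIRED status, and a
#' successor gene at a different locus.
#'
#' @param n_chrom Number of chromosomes (labels I, II, III, IV, V, X, then
#'   chr7, chr8, ...).
#' @param genes_per_chrom Genes per chromosome.
#' @param gene_len_range,intergenic_len_range Length ranges in bp.
#' @param n_paralog_pairs Number of >=`paralog_identity` gene pairs.
#' @param paralog_identity Pairwise identity of paralog pairs, in
#'   `[0.80, 1)`.
#' @param n_retired Number of retired genes (each with a successor).
#' @param desert_len Length of each gene desert in bp.
#' @param seed Integer RNG seed; output is a pure function of the arguments.
#' @return A list: `genome` (named [Biostrings::DNAStringSet]) and `genes`
#'   (gene table with `successor` column; attributes `paralog_pairs` and
#'   `deserts`).
#' @export
generate_genome <- function(n_chrom = 6, genes_per_chrom = 42,
                            gene_len_range = c(450, 900),
                            intergenic_len_range = c(120, 300),
                            n_paralog_pairs = 12, paralog_identity = 0.96,
                            n_retired = 24, desert_len = 3000, seed = 1) {
  if (paralog_identity < 0.80 || paralog_identity >= 1)
    stop("paralog_identity must lie in [0.80, 1)")
  n_genes <- n_chrom * genes_per_chrom
  if (2L * n_paralog_pairs + 2L * n_retired > n_genes)
    stop("infeasible packing: not enough gene slots for paralogs and retirements")
  if (n_paralog_pairs > 0 && n_chrom < 2)
    stop("infeasible packing: paralog pairs need at least 2 chromosomes")
  .with_seed(seed, salt = 271828L, code = {
    labels <- c("I", "II", "III", "IV", "V", "X",
                paste0("chr", seq_len(max(0, n_chrom - 6)) + 6L))[seq_len(n_chrom)]
    thermo <- thermo_params()

    # slot layout: (chrom, index-within-chrom) for every gene
    slot_chrom <- rep(seq_len(n_chrom), each = genes_per_chrom)
    slot_len <- sample(seq(gene_len_range[1], gene_len_range[2]), n_genes,
                       replace = TRUE)
    slot_seq <- character(n_genes)
    slot_id <- character(n_genes)
    for (g in seq_len(n_genes)) {
      ci <- slot_chrom[g]; within <- g - (ci - 1L) * genes_per_chrom
      slot_id[g] <- sprintf("%s%02dH%d.%d", LETTERS[ci],
                            (within - 1L) %/% 4L + 1L, ci,
                            (within - 1L) %% 4L + 1L)
    }

    # paralog pairs on different chromosomes, with tuned shared primer windows
    paralog <- NULL
    pool <- seq_len(n_genes)
    if (n_paralog_pairs > 0) {
      rows <- list()
      for (k in seq_len(n_paralog_pairs)) {
        c1 <- (k - 1L) %% n_chrom + 1L
        c2 <- k %% n_chrom + 1L
        a <- pool[slot_chrom[pool] == c1][1]
        b <- pool[slot_chrom[pool] == c2][1]
        if (is.na(a) || is.na(b))
          stop("infeasible packing: cannot place paralog pair ", k)
        pool <- setdiff(pool, c(a, b))
        len <- max(slot_len[a], 560L)
        size <- len - 60L
        pair <- NULL
        for (try in 1:80) {
          seqA <- .rand_dna(len)
          pair <- .tune_pair(seqA, w0 = 20L, size = size, thermo)
          if (!is.null(pair)) break
        }
        if (is.null(pair))
          stop("infeasible packing: no primer-compatible paralog sequence")
        seqB <- .mutate_dna(seqA, 1 - paralog_identity)
        # primer windows are exact copies in both members
        substr(seqB, 21L, 20L + nchar(pair$fwd)) <-
          substr(seqA, 21L, 20L + nchar(pair$fwd))
        substr(seqB, 20L + size - nchar(pair$rev) + 1L, 20L + size) <-
          substr(seqA, 20L + size - nchar(pair$rev) + 1L, 20L + size)
        slot_len[c(a, b)] <- len
        slot_seq[a] <- seqA; slot_seq[b] <- seqB
        rows[[k]] <- data.frame(gene1 = slot_id[a], gene2 = slot_id[b],
                                fwd = pair$fwd, rev = pair$rev,
                                w0 = pair$w0, size = size,
                                stringsAsFactors = FALSE)
      }
      paralog <- do.call(rbind, rows)
    }

    # retired genes and their successors, among the remaining slots
    retired_slots <- if (n_retired > 0) sample(pool, n_retired) else integer(0)
    pool <- setdiff(pool, retired_slots)
    successor_slots <- if (n_retired > 0) sample(pool, n_retired) else integer(0)
    status <- rep("ALIVE", n_genes)
    successor <- rep(NA_character_, n_genes)
    for (k in seq_along(retired_slots)) {
      r <- retired_slots[k]
      slot_id[r] <- sprintf("Y%dD%02d_%d.a", slot_chrom[r], k, 400 + k)
      status[r] <- "RETIRED"
      successor[r] <- slot_id[successor_slots[k]]
    }

    # fill in remaining gene sequences
    for (g in seq_len(n_genes))
      if (slot_seq[g] == "") slot_seq[g] <- .rand_dna(slot_len[g])

    # assemble chromosomes: gap gene gap gene ... with two deserts
    chrom_seqs <- character(n_chrom)
    gene_start <- integer(n_genes)
    deserts <- list()
    gap <- function() .rand_dna(sample(
      seq(intergenic_len_range[1], intergenic_len_range[2]), 1))
    for (ci in seq_len(n_chrom)) {
      idx <- which(slot_chrom == ci)
      parts <- character(0); pos <- 0L
      desert_after <- if (length(idx) > 0)
        unique(pmax(1L, ceiling(length(idx) * c(1, 2) / 3))) else integer(0)
      add <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
      add(gap())
      for (j in seq_along(idx)) {
        g <- idx[j]
        gene_start[g] <- pos
        add(slot_seq[g])
        add(gap())
        if (j %in% desert_after) {
          deserts[[length(deserts) + 1L]] <-
            data.frame(chrom = labels[ci], start = pos, end = pos + desert_len)
          add(.rand_dna(desert_len))
          add(gap())
        }
      }
      if (length(idx) == 0L) {           # all-intergenic chromosome
        deserts[[length(deserts) + 1L]] <-
          data.frame(chrom = labels[ci], start = pos, end = pos + desert_len)
        add(.rand_dna(desert_len))
      }
      chrom_seqs[ci] <- paste(parts, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(chrom_seqs)
    names(genome) <- labels

    genes <- .new_gene_table(
      gene_id = slot_id, chrom = labels[slot_chrom],
      start = gene_start, end = gene_start + slot_len,
      strand = rep(c("+", "-"), length.out = n_genes),
      status = status, successor = successor)
    attr(genes, "paralog_pairs") <- paralog
    attr(genes, "deserts") <- if (length(deserts) > 0)
      do.call(rbind, deserts) else NULL
    list(genome = genome, genes = genes)
  })
}

# sequential sub-allocator over desert intervals, avoiding a chromosome
.desert_allocator <- function(deserts) {
  ptr <- deserts$start + 25L
  function(len, not_chrom = NULL) {
    for (d in seq_len(nrow(deserts))) {
      if (!is.null(not_chrom) && deserts$chrom[d] == not_chrom) next
      if (ptr[d] + len + 25L <= deserts$end[d]) {
        at <- ptr[d]; ptr[d] <<- ptr[d] + len + 40L
        return(list(chrom = deserts$chrom[d], start = at))
      }
    }
    stop("unsatisfiable class: gene deserts exhausted")
  }
}

#' Generate a plated clone library with injected defects
#'
#' Assigns clones to 384-well plates (row-major), designs primer pairs per
#' clone according to its defect class, plants the genomic decoy loci that
#' the nonspecific class requires (inside gene deserts, on a different
#' chromosome than the annotated gene), and verifies each design with the
#' package's own in-silico PCR engine.  Because decoy planting edits the
#' genome, the (possibly modified) genome is returned alongside the clones.
#'
#' @param genome,genes Output of [generate_genome()].
#' @param n_clones Number of clones.
#' @param defects A [defect_spec()].
#' @param plate_labels Chromosome labels cycled over successive plates.
#' @param seed Integer RNG seed.
#' @return A list: `clones` (clone table as from [read_clone_table()]),
#'   `truth` (data.frame `clone_name, class, actual_gene, shift_axis,
#'   shift_offset, partner_clone`), and `genome` (with decoys planted).
#' @export
generate_library <- function(genome, genes, n_clones, defects = defect_spec(),
                             plate_labels = names(genome), seed = 1) {
  .with_seed(seed, salt = 628318L, code = {
    thermo <- thermo_params()
    fr <- defects$fractions
    n_class <- setNames(as.integer(round(fr * n_clones)), names(fr))
    if (sum(n_class) > n_clones) stop("defect fractions sum above 1")
    paralog <- attr(genes, "paralog_pairs")
    deserts <- attr(genes, "deserts")
    if (n_class[["HOMOLOG_COMIGRATION"]] > 0 &&
        (is.null(paralog) || nrow(paralog) < n_class[["HOMOLOG_COMIGRATION"]]))
      stop("unsatisfiable class: not enough paralog pairs in the genome")
    retired_ids <- genes$gene_id[genes$status == "RETIRED"]
    if (n_class[["RETIRED_REMAPPED"]] > length(retired_ids))
      stop("unsatisfiable class: not enough retired genes")
    if ((n_class[["NONSPECIFIC_PRIMERS"]] > 0 ||
         n_class[["INTERGENIC_AMPLICON"]] > 0) && is.null(deserts))
      stop("unsatisfiable class: genome has no gene desert")

    # well geometry, row-major within successive 384-well plates
    well_of <- function(i) {
      p <- (i - 1L) %/% 384L
      w <- (i - 1L) %% 384L
      list(chrom_label = plate_labels[p %% length(plate_labels) + 1L],
           plate_no = p %/% length(plate_labels) + 1L,
           row_i = w %/% 24L + 1L, col = w %% 24L + 1L)
    }
    same_plate <- function(i, j) (i - 1L) %/% 384L == (j - 1L) %/% 384L

    # class layout: place loading-shift clones (and reserve their partners)
    # first, then scatter the other defects over free wells
    class <- rep("SPECIFIC", n_clones)
    reserved <- rep(FALSE, n_clones)
    shift_info <- list()
    pats <- defects$loading_shift_patterns
    if (n_class[["LOADING_SHIFT"]] > 0) {
      for (k in seq_len(n_class[["LOADING_SHIFT"]])) {
        pat <- pats[[(k - 1L) %% length(pats) + 1L]]
        step <- if (pat$axis == "ROW") 24L * pat$offset else pat$offset
        ok <- which(vapply(seq_len(n_clones), function(i) {
          j <- i + step
          j >= 1L && j <= n_clones && j != i && same_plate(i, j) &&
            (pat$axis == "ROW" || (i - 1L) %% 384L %/% 24L ==
                                  (j - 1L) %% 384L %/% 24L) &&
            class[i] == "SPECIFIC" && !reserved[i] &&
            class[j] == "SPECIFIC" && !reserved[j]
        }, logical(1)))
        if (length(ok) == 0L)
          stop("unsatisfiable class: no free well for loading shift pattern ",
               pat$axis, pat$offset)
        i <- if (length(ok) == 1L) ok else sample(ok, 1L)
        j <- i + step
        class[i] <- "LOADING_SHIFT"
        reserved[c(i, j)] <- TRUE
        shift_info[[length(shift_info) + 1L]] <-
          list(i = i, j = j, axis = pat$axis, offset = pat$offset)
      }
    }
    free <- which(class == "SPECIFIC" & !reserved)
    other <- c("NONSPECIFIC_PRIMERS", "INTERGENIC_AMPLICON",
               "RETIRED_REMAPPED", "EMPTY_VECTOR", "HOMOLOG_COMIGRATION")
    need <- sum(n_class[other])
    if (need > length(free)) stop("not enough wells for requested defects")
    pick <- if (need > 0) sample(free, need) else integer(0)
    class[pick] <- rep(other, n_class[other])

    # gene pools
    paralog_members <- if (is.null(paralog)) character(0) else
      c(paralog$gene1, paralog$gene2)
    alive_pool <- genes$gene_id[genes$status == "ALIVE" &
                                !genes$gene_id %in% paralog_members &
                                !genes$gene_id %in% genes$successor]
    alive_pool <- sample(alive_pool)
    n_plain <- sum(class %in% c("SPECIFIC", "LOADING_SHIFT",
                                "NONSPECIFIC_PRIMERS", "INTERGENIC_AMPLICON",
                                "EMPTY_VECTOR"))
    if (n_plain > length(alive_pool))
      stop("not enough genes for requested clones")
    take_gene <- local({ k <- 0L; function() { k <<- k + 1L; alive_pool[k] } })
    retired_take <- local({ k <- 0L; ids <- sample(retired_ids)
                            function() { k <<- k + 1L; ids[k] } })
    par_take <- local({ k <- 0L; function() { k <<- k + 1L; paralog[k, ] } })

    gseq <- as.character(genome)          # mutable working copy
    alloc <- .desert_allocator(deserts)
    grow <- function(gid) {               # gene row helper
      genes[match(gid, genes$gene_id), ]
    }

    # design primers amplifying [w0+1, w0+size] inside gene `gid`; returns
    # NULL when the gene admits no compliant pair (pathologically AT-rich
    # genes exist at realistic base composition)
    design_in_gene <- function(gid, min_size = 360L) {
      g <- grow(gid)
      glen <- g$end - g$start
      for (try in 1:60) {
        size <- sample(seq(min_size, max(min_size + 1L, glen - 50L)), 1L)
        w0 <- g$start + sample.int(max(1L, glen - size - 20L), 1L) + 9L
        pair <- .tune_pair(gseq[[g$chrom]], w0, size, thermo)
        if (!is.null(pair)) return(c(pair, list(chrom = g$chrom)))
      }
      NULL
    }

    # draw genes from the pool until one admits a primer pair
    design_in_fresh_gene <- function() {
      repeat {
        gid <- take_gene()
        if (is.na(gid)) stop("not enough genes for requested clones")
        p <- design_in_gene(gid)
        if (!is.null(p)) return(c(p, list(gene = gid)))
      }
    }

    annotated <- character(n_clones)
    fwd <- character(n_clones); rev <- character(n_clones)
    truth_class <- class
    actual <- rep(NA_character_, n_clones)
    shift_axis <- rep(NA_character_, n_clones)
    shift_offset <- rep(NA_integer_, n_clones)
    partner <- rep(NA_character_, n_clones)

    # pass 1: genes + primer sequences (and decoy planting) per clone.
    # shift partners are designed first: the partner's gene must admit two
    # independent primer windows (one for the partner clone, one for the
    # displaced clone), so a hostile gene forces a redraw for the pair
    shift_partner_gene <- rep(NA_character_, n_clones)
    for (s in shift_info) {
      repeat {
        g <- take_gene()
        if (is.na(g)) stop("not enough genes for requested clones")
        p_partner <- design_in_gene(g)
        if (is.null(p_partner)) next
        p_shift <- design_in_gene(g)
        if (is.null(p_shift)) next
        annotated[s$j] <- g               # partner keeps its own gene
        fwd[s$j] <- p_partner$fwd; rev[s$j] <- p_partner$rev
        actual[s$j] <- g
        shift_partner_gene[s$i] <- g
        fwd[s$i] <- p_shift$fwd; rev[s$i] <- p_shift$rev
        actual[s$i] <- g
        annotated[s$i] <- take_gene()     # the gene this well was meant for
        if (is.na(annotated[s$i]))
          stop("not enough genes for requested clones")
        break
      }
    }
    for (i in seq_len(n_clones)) {
      cl <- class[i]
      if (cl == "LOADING_SHIFT") next     # designed above
      if (cl == "SPECIFIC" && fwd[i] != "") next  # shift partner
      if (cl == "SPECIFIC") {
        p <- design_in_fresh_gene()
        annotated[i] <- p$gene
        fwd[i] <- p$fwd; rev[i] <- p$rev
        actual[i] <- annotated[i]
      } else if (cl == "RETIRED_REMAPPED") {
        repeat {
          rid <- retired_take()
          if (is.na(rid))
            stop("unsatisfiable class: no retired gene with a",
                 " primer-compatible successor left")
          succ <- genes$successor[match(rid, genes$gene_id)]
          p <- design_in_gene(succ)
          if (!is.null(p)) break
        }
        annotated[i] <- rid
        fwd[i] <- p$fwd; rev[i] <- p$rev
        actual[i] <- succ
      } else if (cl == "HOMOLOG_COMIGRATION") {
        pr <- par_take()
        annotated[i] <- pr$gene1
        fwd[i] <- pr$fwd; rev[i] <- pr$rev
        actual[i] <- pr$gene1
      } else if (cl == "INTERGENIC_AMPLICON") {
        annotated[i] <- take_gene()
        if (is.na(annotated[i])) stop("not enough genes for requested clones")
        size <- sample(380:520, 1L)
        pair <- NULL
        for (try in 1:8) {               # jitter within the slot, then give
          slot <- alloc(size + 40L)      # the slot up and draw a fresh one
          for (j in seq(0L, 36L, by = 4L)) {
            pair <- .tune_pair(gseq[[slot$chrom]], slot$start + j, size,
                               thermo)
            if (!is.null(pair)) break
          }
          if (!is.null(pair)) break
        }
        if (is.null(pair)) stop("unsatisfiable class: intergenic design failed")
        fwd[i] <- pair$fwd; rev[i] <- pair$rev
      } else if (cl == "EMPTY_VECTOR") {
        annotated[i] <- take_gene()
        if (is.na(annotated[i])) stop("not enough genes for requested clones")
        repeat {                         # dG-clean so zero score comes from
          fwd[i] <- .rand_dna(20, at = 0.5)   # the missing amplicon, not the
          rev[i] <- .rand_dna(20, at = 0.5)   # 3'-end rule
          if (dg_3prime_end(fwd[i], thermo) >= -9 &&
              dg_3prime_end(rev[i], thermo) >= -9) break
        }
      } else if (cl == "NONSPECIFIC_PRIMERS") {
        p <- design_in_fresh_gene()
        annotated[i] <- p$gene
        fwd[i] <- p$fwd; rev[i] <- p$rev
        # plant a same-size decoy with exact primer footprints and random
        # interior in a desert on another chromosome
        slot <- alloc(p$size, not_chrom = p$chrom)
        interior <- .rand_dna(p$size - nchar(p$fwd) - nchar(p$rev))
        decoy <- paste0(p$fwd, interior, reverse_complement(p$rev))
        substr(gseq[[slot$chrom]], slot$start + 1L,
               slot$start + p$size) <- decoy
        actual[i] <- NA_character_
      }
    }
    for (s in shift_info) {
      shift_axis[s$i] <- s$axis
      shift_offset[s$i] <- s$offset
      partner[s$i] <- annotated[s$j]     # resolved to clone name below
    }

    genome2 <- Biostrings::DNAStringSet(gseq)
    names(genome2) <- names(genome)

    # pass 2: verify designs against the final genome
    expected_n <- c(SPECIFIC = 1L, LOADING_SHIFT = 1L, RETIRED_REMAPPED = 1L,
                    HOMOLOG_COMIGRATION = 2L, INTERGENIC_AMPLICON = 1L,
                    EMPTY_VECTOR = 0L, NONSPECIFIC_PRIMERS = 2L)
    for (i in seq_len(n_clones)) {
      amp <- enumerate_amplicons(fwd[i], rev[i], genome2, thermo = thermo)
      if (nrow(amp) != expected_n[[class[i]]])
        stop("library generation failed verification for clone ", i,
             " (", class[i], "): ", nrow(amp), " amplicons [",
             paste(amp$chrom, amp$start, amp$size, round(amp$ppc, 2),
                   sep = ":", collapse = " "), "]")
    }

    loc <- lapply(seq_len(n_clones), well_of)
    locdf <- data.frame(
      chrom_label = vapply(loc, `[[`, character(1), "chrom_label"),
      plate_no = vapply(loc, `[[`, integer(1), "plate_no"),
      row_i = vapply(loc, `[[`, integer(1), "row_i"),
      col = vapply(loc, `[[`, integer(1), "col"))
    locdf$row <- .ROW_LETTERS[locdf$row_i]
    clones <- data.frame(
      clone_name = annotated, fwd = fwd, rev = rev,
      annotated_gene = annotated,
      location = format_plate_location(locdf),
      locdf[c("chrom_label", "plate_no", "row", "row_i", "col")],
      stringsAsFactors = FALSE)
    if (anyDuplicated(clones$clone_name))
      stop("internal error: duplicate clone names")
    truth <- data.frame(
      clone_name = annotated, class = truth_class, actual_gene = actual,
      shift_axis = shift_axis, shift_offset = shift_offset,
      partner_clone = partner, stringsAsFactors = FALSE)
    list(clones = clones, truth = truth, genome = genome2)
  })
}

#' Simulate direct-sequencing validation of a clone library
#'
#' Maps each clone's ground-truth defect class to the sequencing outcome
#' taxonomy (`RELIABLE`, `REMAPPED_RETIRED`, `REMAPPED_WRONG_INSERT`,
#' `UNRELIABLE`) and perturbs each record to a different outcome with
#' probability `misread_rate`.
#'
#' @param clones,truth Output of [generate_library()].
#' @param misread_rate Per-record probability of a misread, in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return A data.frame `clone_name, outcome, sequenced_gene`.
#' @export
simulate_sequencing <- function(clones, truth, misread_rate = 0, seed = 1) {
  if (misread_rate < 0 || misread_rate >= 1)
    stop("misread_rate must lie in [0, 1)")
  if (nrow(clones) == 0L)
    return(data.frame(clone_name = character(0), outcome = character(0),
                      sequenced_gene = character(0), stringsAsFactors = FALSE))
  map <- c(SPECIFIC = "RELIABLE", HOMOLOG_COMIGRATION = "RELIABLE",
           RETIRED_REMAPPED = "REMAPPED_RETIRED",
           LOADING_SHIFT = "REMAPPED_WRONG_INSERT",
           NONSPECIFIC_PRIMERS = "UNRELIABLE",
           INTERGENIC_AMPLICON = "UNRELIABLE",
           EMPTY_VECTOR = "UNRELIABLE")
  .with_seed(seed, salt = 141421L, code = {
    outcome <- unname(map[truth$class])
    lv <- c("RELIABLE", "REMAPPED_RETIRED", "REMAPPED_WRONG_INSERT",
            "UNRELIABLE")
    flip <- stats::runif(nrow(truth)) < misread_rate
    for (i in which(flip))
      outcome[i] <- sample(setdiff(lv, outcome[i]), 1L)
    data.frame(clone_name = truth$clone_name, outcome = outcome,
               sequenced_gene = truth$actual_gene, stringsAsFactors = FALSE)
  })
}
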