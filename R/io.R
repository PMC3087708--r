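# Readers/writers for the external representations the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; the 1-based inclusive
# convention appears only at GFF3 boundaries.

#' Read a genome FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (uppercased; `N` allowed),
#'   records in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("FASTA format error in ", path,
                                            ": ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA format error: no records in ", path)
  # first whitespace token of the header is the chromosome id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(names(seqs) == ""))
    stop("FASTA format error: record with empty id in ", path)
  if (any(Biostrings::width(seqs) == 0L))
    stop("FASTA format error: empty sequence record in ", path)
  if (anyDuplicated(names(seqs)))
    stop("FASTA format error: duplicate chromosome id in ", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", as.character(seqs))
  if (any(bad))
    stop("FASTA format error: characters outside {A,C,G,T,N} in record ",
         names(seqs)[bad][1])
  seqs
}

.new_gene_table <- function(gene_id, chrom, start, end, strand, status,
                            successor = NA_character_) {
  data.frame(gene_id = gene_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, status = status,
             successor = successor, stringsAsFactors = FALSE)
}

.validate_gene_table <- function(genes) {
  if (anyDuplicated(genes$gene_id))
    stop("gene table format error: duplicate gene_id")
  if (any(genes$start < 0L) || any(genes$start >= genes$end))
    stop("gene table format error: start must satisfy 0 <= start < end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene table format error: strand must be '+' or '-'")
  if (!all(genes$status %in% c("ALIVE", "RETIRED")))
    stop("gene table format error: status must be ALIVE or RETIRED")
  genes
}

#' Read a gene annotation table
#'
#' Accepts either GFF3 (`type == "gene"` features; `status=` and `successor=`
#' attributes honored, status defaulting to ALIVE) or a 5/6-column TSV with
#' header `gene_id chrom start end strand [status]`.  File coordinates are
#' 1-based inclusive; the returned table stores 0-based half-open
#' `start`/`end`.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return A data.frame with columns `gene_id, chrom, start, end, strand,
#'   status, successor`.
#' @export
read_gene_table <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop("gene table format error: no gene features")
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(md)) as.character(md$ID) else
      as.character(md$Name)
    status <- if ("status" %in% names(md))
      toupper(as.character(md$status)) else rep(NA_character_, length(gr))
    status[is.na(status)] <- "ALIVE"
    successor <- if ("successor" %in% names(md))
      as.character(md$successor) else rep(NA_character_, length(gr))
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*"))
      stop("gene table format error: unknown strand for gene ",
           ids[strand == "*"][1])
    genes <- .new_gene_table(ids, as.character(GenomicRanges::seqnames(gr)),
                             BiocGenerics::start(gr) - 1L,
                             BiocGenerics::end(gr),
                             strand, status, successor)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(tab)))
      stop("gene table format error: TSV needs columns ",
           paste(need, collapse = ", "))
    if (any(tab$start > tab$end))
      stop("gene table format error: start > end")
    if (!all(tab$strand %in% c("+", "-")))
      stop("gene table format error: unknown strand '",
           setdiff(tab$strand, c("+", "-"))[1], "'")
    status <- if ("status" %in% names(tab)) toupper(tab$status) else
      rep("ALIVE", nrow(tab))
    successor <- if ("successor" %in% names(tab)) tab$successor else
      rep(NA_character_, nrow(tab))
    successor[successor %in% c("", "NA")] <- NA_character_
    genes <- .new_gene_table(tab$gene_id, tab$chrom, tab$start - 1L, tab$end,
                             tab$strand, status, successor)
  }
  .validate_gene_table(genes)
}

#' Write a gene table as TSV (1-based inclusive coordinates)
#'
#' Inverse of `read_gene_table(..., dialect = "tsv")`.
#'
#' @param genes A gene table.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start + 1L, end = genes$end,
                    strand = genes$strand, status = genes$status,
                    successor = ifelse(is.na(genes$successor), "NA",
                                       genes$successor))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- 384-well plate locations ------------------------------------------------

.ROW_LETTERS <- LETTERS[1:16]

#' Parse plate-location literals like "IV-2B04"
#'
#' Locations follow the 384-well convention
#' `<chrom label>-<plate number><row letter A-P><2-digit column 1-24>`.
#'
#' @param x Character vector of location literals.
#' @return A data.frame with columns `chrom_label, plate_no, row, col`
#'   (`row` as letter; `row_i` as integer A=1..P=16).
#' @examples
#' parse_plate_location("IV-2B04")
#' @export
parse_plate_location <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z0-9]+)-([0-9]+)([A-P])([0-9]{2})$", x))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad))
    stop("malformed plate location: '", x[bad][1], "'")
  chrom_label <- vapply(m, `[`, character(1), 2L)
  plate_no <- as.integer(vapply(m, `[`, character(1), 3L))
  row <- vapply(m, `[`, character(1), 4L)
  col <- as.integer(vapply(m, `[`, character(1), 5L))
  if (any(plate_no < 1L))
    stop("malformed plate location: plate number must be positive")
  if (any(col < 1L | col > 24L))
    stop("malformed plate location: column outside 1..24 in '",
         x[col < 1L | col > 24L][1], "'")
  data.frame(chrom_label = chrom_label, plate_no = plate_no, row = row,
             row_i = match(row, .ROW_LETTERS), col = col,
             stringsAsFactors = FALSE)
}

#' Format plate locations back to their text form
#'
#' @param loc A data.frame as returned by [parse_plate_location()].
#' @return Character vector of literals such as `"IV-2B04"`.
#' @export
format_plate_location <- function(loc) {
  sprintf("%s-%d%s%02d", loc$chrom_label, loc$plate_no, loc$row, loc$col)
}

#' Read a clone/primer table
#'
#' TSV with header `clone_name fwd rev annotated_gene location`; the location
#' column uses plate literals like `"X-6I10"`.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `clone_name, fwd, rev, annotated_gene,
#'   location, chrom_label, plate_no, row, row_i, col`.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone_name", "fwd", "rev", "annotated_gene", "location")
  if (!all(need %in% names(tab)))
    stop("clone table format error: TSV needs columns ",
         paste(need, collapse = ", "))
  for (col in c("fwd", "rev")) {
    tab[[col]] <- toupper(tab[[col]])
    bad <- nchar(tab[[col]]) < 10L | grepl("[^ACGT]", tab[[col]])
    if (any(bad))
      stop("clone table format error: invalid ", col, " primer in row ",
           which(bad)[1], " (clone ", tab$clone_name[which(bad)[1]], ")")
  }
  loc <- tryCatch(parse_plate_location(tab$location), error = function(e) {
    stop("clone table format error: ", conditionMessage(e))
  })
  cbind(tab[need], loc)
}

#' Write a per-clone evaluation table
#'
#' One TSV row per clone: name, score, category, flags, predicted targets and
#' amplicon count, ordered deterministically by plate then well (row-major).
#'
#' @param evaluations A clone-evaluation table from [evaluate_library()].
#' @param path Output path.
#' @export
write_evaluation_table <- function(evaluations, path) {
  cols <- c("clone_name", "location", "score", "category", "flags",
            "predicted_targets", "n_amplicons")
  if (nrow(evaluations) > 0) {
    ord <- order(evaluations$chrom_label, evaluations$plate_no,
                 evaluations$row_i, evaluations$col)
    out <- evaluations[ord, cols]
  } else {
    out <- evaluations[, cols, drop = FALSE]
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write evaluation table: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genome sequences as FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
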