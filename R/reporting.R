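# Aggregation of clone evaluations into the deliverable tables: category
# summaries, sequencing-validation cross-tabulations and per-plate maps.
# Percentages are round-half-up to 2 decimals throughout.

.pct <- function(count, denom) {
  d <- rep_len(denom, length(count))
  out <- rep(NA_real_, length(count))
  ok <- d > 0
  out[ok] <- .round_half_up(100 * count[ok] / d[ok], 2)
  out
}

.CATEGORIES <- c("RELIABLE", "MARGINAL", "UNRELIABLE")
.OUTCOMES <- c("RELIABLE", "REMAPPED_RETIRED", "REMAPPED_WRONG_INSERT",
               "UNRELIABLE")

#' Category summary from bare counts
#'
#' The arithmetic core of [summary_table()]: takes per-category clone counts
#' (and optionally per-category sequenced and remapped counts) and computes
#' the summary with its percentages.  Group percentages are relative to the
#' library total; sequenced/remapped percentages are relative to the group's
#' own count, and to the library total on the Total row.
#'
#' @param n Named numeric vector of clone counts, names
#'   `RELIABLE, MARGINAL, UNRELIABLE`.
#' @param sequenced,remapped Optional vectors with the same names.
#' @return A data.frame with rows Reliable/Marginal/Unreliable/Total and
#'   count/percentage columns.
#' @export
summary_counts_table <- function(n, sequenced = NULL, remapped = NULL) {
  n <- n[.CATEGORIES]; n[is.na(n)] <- 0
  total <- sum(n)
  out <- data.frame(
    group = c("Reliable", "Marginal", "Unreliable", "Total"),
    n = c(n, total),
    pct = c(.pct(n, total), ifelse(total > 0, 100, NA_real_)))
  if (!is.null(sequenced)) {
    s <- sequenced[.CATEGORIES]; s[is.na(s)] <- 0
    out$sequenced <- c(s, sum(s))
    out$sequenced_pct <- c(.pct(s, n), .pct(sum(s), total))
  }
  if (!is.null(remapped)) {
    r <- remapped[.CATEGORIES]; r[is.na(r)] <- 0
    out$remapped <- c(r, sum(r))
    out$remapped_pct <- c(.pct(r, n), .pct(sum(r), total))
  }
  rownames(out) <- NULL
  out
}

#' Category summary of a library evaluation
#'
#' Counts clones per reliability category with percentages of the library
#' total, plus the number carrying the remap ("R") flag per category, and
#' optionally the number sequenced.
#'
#' @param evaluations An evaluation table from [evaluate_library()].
#' @param validation Optional validation records ([simulate_sequencing()]):
#'   clones present there count as sequenced.
#' @return See [summary_counts_table()].
#' @export
summary_table <- function(evaluations, validation = NULL) {
  cat_n <- function(sel) {
    v <- table(factor(evaluations$category[sel], levels = .CATEGORIES))
    stats::setNames(as.numeric(v), .CATEGORIES)
  }
  n <- cat_n(TRUE)
  remap <- grepl("REMAPPED|NO_TARGET", evaluations$flags)
  remapped <- cat_n(remap)
  sequenced <- NULL
  if (!is.null(validation))
    sequenced <- cat_n(evaluations$clone_name %in% validation$clone_name)
  summary_counts_table(n, sequenced, remapped)
}

#' Validation cross-tabulation from bare counts
#'
#' @param counts Numeric matrix: rows `Green, Yellow, Red` (predicted),
#'   columns `RELIABLE, REMAPPED_RETIRED, REMAPPED_WRONG_INSERT, UNRELIABLE`
#'   (sequencing outcome).
#' @return A data.frame with a Summary row appended and, per outcome, count
#'   and percentage (of the row total) columns.
#' @export
crosstab_counts_table <- function(counts) {
  counts <- counts[c("Green", "Yellow", "Red"), .OUTCOMES, drop = FALSE]
  m <- rbind(counts, Summary = colSums(counts))
  tot <- rowSums(m)
  out <- data.frame(category = rownames(m), n = as.numeric(tot))
  for (oc in .OUTCOMES) {
    out[[oc]] <- as.numeric(m[, oc])
    out[[paste0(oc, "_pct")]] <- .pct(m[, oc], tot)
  }
  rownames(out) <- NULL
  out
}

#' Cross-tabulate predicted categories against sequencing outcomes
#'
#' @param evaluations An evaluation table from [evaluate_library()].
#' @param validation Validation records (`clone_name`, `outcome`), e.g. from
#'   [simulate_sequencing()].
#' @return See [crosstab_counts_table()].
#' @export
validation_crosstab <- function(evaluations, validation) {
  idx <- match(validation$clone_name, evaluations$clone_name)
  if (anyNA(idx))
    stop("validation record for unknown clone: ",
         validation$clone_name[is.na(idx)][1])
  color <- c(RELIABLE = "Green", MARGINAL = "Yellow", UNRELIABLE = "Red")
  pred <- factor(color[evaluations$category[idx]],
                 levels = c("Green", "Yellow", "Red"))
  oc <- factor(validation$outcome, levels = .OUTCOMES)
  crosstab_counts_table(unclass(table(pred, oc)))
}

#' Render one 384-well plate as a traffic-light grid
#'
#' Cell glyphs are `G`/`Y`/`R` for green (reliable), yellow (marginal) and
#' red (unreliable) clones, with an `R` suffix for clones needing remapping
#' (remapped or no gene hit) and a tick/cross suffix for
#' sequencing-confirmed reliable/unreliable clones; blank wells show a dot.
#'
#' @param evaluations An evaluation table from [evaluate_library()].
#' @param chrom_label,plate_no Plate identity (e.g. `"IV"`, `2`).
#' @param validation Optional validation records.
#' @param html If TRUE, return an HTML `<table>` string with colored cells
#'   instead of a character matrix.
#' @return A 16x24 character matrix (rows A-P), or an HTML string.
#' @export
plate_map <- function(evaluations, chrom_label, plate_no, validation = NULL,
                      html = FALSE) {
  sel <- evaluations$chrom_label == chrom_label &
    evaluations$plate_no == plate_no
  if (!any(sel)) stop("unknown plate: ", chrom_label, "-", plate_no)
  ev <- evaluations[sel, ]
  glyph <- c(RELIABLE = "G", MARGINAL = "Y", UNRELIABLE = "R")
  grid <- matrix(".", nrow = 16, ncol = 24,
                 dimnames = list(.ROW_LETTERS, sprintf("%02d", 1:24)))
  colors <- matrix("white", nrow = 16, ncol = 24)
  palette <- c(RELIABLE = "#8f8", MARGINAL = "#ff8", UNRELIABLE = "#f88")
  for (i in seq_len(nrow(ev))) {
    g <- glyph[[ev$category[i]]]
    if (grepl("REMAPPED|NO_TARGET", ev$flags[i])) g <- paste0(g, "R")
    if (!is.null(validation)) {
      j <- match(ev$clone_name[i], validation$clone_name)
      if (!is.na(j)) {
        if (validation$outcome[j] == "RELIABLE") g <- paste0(g, "✓")
        if (validation$outcome[j] == "UNRELIABLE") g <- paste0(g, "✗")
      }
    }
    grid[ev$row_i[i], ev$col[i]] <- g
    colors[ev$row_i[i], ev$col[i]] <- palette[[ev$category[i]]]
  }
  if (!html) return(grid)
  rows <- vapply(seq_len(16), function(r) {
    cells <- vapply(seq_len(24), function(c)
      sprintf('<td style="background:%s">%s</td>', colors[r, c], grid[r, c]),
      character(1))
    paste0("<tr><th>", .ROW_LETTERS[r], "</th>",
           paste(cells, collapse = ""), "</tr>")
  }, character(1))
  paste0('<table border="1"><tr><th></th>',
         paste0("<th>", sprintf("%02d", 1:24), "</th>", collapse = ""),
         "</tr>", paste(rows, collapse = ""), "</table>")
}
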