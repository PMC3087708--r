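# The penalty ledger: each clone starts at 100 and accumulates penalties
# until zero.  A dangerously stable 3' end (pentamer dG below -9 kcal/mol on
# either primer) or a pair with no surviving amplicon zeroes the score
# outright; each co-migrating group of two or more amplicons costs
# (100 - similarity score of the group).  Scores are integers; categories are
# green (reliable, >= 95), yellow (marginal, 10 < s < 95), red (unreliable,
# <= 10).

.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Score a clone on the penalty ledger
#'
#' @param dg3_fwd,dg3_rev 3'-pentamer free energies of the two primers, in
#'   kcal/mol (see [dg_3prime_end()]).
#' @param n_amplicons Number of amplicons surviving the in-silico PCR
#'   filters.
#' @param group_similarities Numeric vector with one similarity score
#'   (0-100, see [similarity_score()]) per co-migrating group of >= 2
#'   amplicons; empty when all bands are resolvable.
#' @param dg_threshold 3'-end discard threshold in kcal/mol (default -9).
#' @return A list of class `penalty_ledger`: `initial` (100), `entries`
#'   (data.frame `rule, penalty, note`), `final_score` (integer in 0..100).
#' @export
score_clone <- function(dg3_fwd, dg3_rev, n_amplicons,
                        group_similarities = numeric(0),
                        dg_threshold = -9) {
  entries <- data.frame(rule = character(0), penalty = numeric(0),
                        note = character(0), stringsAsFactors = FALSE)
  add <- function(rule, penalty, note) {
    rbind(entries, data.frame(rule = rule, penalty = penalty, note = note,
                              stringsAsFactors = FALSE))
  }
  if (dg3_fwd < dg_threshold || dg3_rev < dg_threshold) {
    which_p <- paste(c("fwd", "rev")[c(dg3_fwd, dg3_rev) < dg_threshold],
                     collapse = "+")
    entries <- add("DG3_END", 100,
                   sprintf("3' pentamer dG below %g kcal/mol (%s)",
                           dg_threshold, which_p))
  } else if (n_amplicons == 0L) {
    entries <- add("NO_AMPLICON", 100, "no amplicon survives the filters")
  } else {
    for (s in group_similarities) {
      s_int <- .round_half_up(s)
      entries <- add("COMIGRATION", 100 - s_int,
                     sprintf("co-migrating group, similarity %d", s_int))
    }
  }
  final <- max(0L, min(100L, as.integer(100 - sum(entries$penalty))))
  structure(list(initial = 100L, entries = entries,
                 final_score = final),
            class = "penalty_ledger")
}

#' Replay a penalty ledger from its entries
#'
#' Audit helper: recomputes the final score from `initial` and the recorded
#' penalties.
#'
#' @param ledger A `penalty_ledger`.
#' @return Integer score in 0..100.
#' @export
replay_ledger <- function(ledger) {
  max(0L, min(100L, as.integer(ledger$initial - sum(ledger$entries$penalty))))
}

#' Classify a reliability score into green/yellow/red
#'
#' @param score Integer score in 0..100 (vectorized).
#' @return `"RELIABLE"` (score >= 95), `"MARGINAL"` (10 < score < 95) or
#'   `"UNRELIABLE"` (score <= 10).
#' @export
classify <- function(score) {
  if (any(score < 0 | score > 100)) stop("score must lie in [0, 100]")
  ifelse(score >= 95, "RELIABLE",
         ifelse(score <= 10, "UNRELIABLE", "MARGINAL"))
}

#' Remapping flags from predicted targets
#'
#' @param annotated_gene The gene the clone is annotated to.
#' @param target_ids Character vector of predicted target gene ids (no
#'   `INTERGENIC` sentinel; may be empty).
#' @return Character vector, subset of
#'   `c("REMAPPED", "NO_TARGET", "MULTI_TARGET")`: `NO_TARGET` when no gene
#'   is hit at all, `REMAPPED` when genes are hit but the annotated gene is
#'   not among them, `MULTI_TARGET` when two or more distinct genes are hit.
#' @export
remap_flags <- function(annotated_gene, target_ids) {
  target_ids <- setdiff(unique(target_ids), "INTERGENIC")
  flags <- character(0)
  if (length(target_ids) == 0L) return("NO_TARGET")
  if (!annotated_gene %in% target_ids) flags <- c(flags, "REMAPPED")
  if (length(target_ids) >= 2L) flags <- c(flags, "MULTI_TARGET")
  flags
}
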