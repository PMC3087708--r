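# Nearest-neighbor DNA duplex thermodynamics used by the in-silico PCR engine.
#
# Two published parameter sets are carried:
#   * unified_1998  -- SantaLucia's unified dH/dS/dG37 set, used for duplex
#     melting temperatures with a monovalent-salt entropy correction.
#   * breslauer_1986 -- the Breslauer dG37 stack set, used by default for the
#     3'-end pentamer stability rule (its stacks are strong enough that four
#     Watson-Crick stacks can cross the -9 kcal/mol discard threshold).
# Tables are keyed by the 5'->3' dinucleotide on the primer strand; values for
# a dinucleotide and its reverse complement are identical by duplex symmetry.

.revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.fill_symmetric <- function(tbl) {
  out <- tbl
  for (d in c("TT", "TG", "AC", "AG", "TC", "CC")) out[d] <- tbl[.revcomp_chr(d)]
  out
}

# SantaLucia (1998) unified parameters: dH kcal/mol, dS cal/(mol K), dG37 kcal/mol
.NN_UNIFIED_DH <- .fill_symmetric(c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
  CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0))
.NN_UNIFIED_DS <- .fill_symmetric(c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
  CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9))
.NN_UNIFIED_DG <- .fill_symmetric(c(
  AA = -1.00, AT = -0.88, TA = -0.58, CA = -1.45, GT = -1.44,
  CT = -1.28, GA = -1.30, CG = -2.17, GC = -2.24, GG = -1.84))

# Breslauer (1986) stack free energies, dG37 kcal/mol
.NN_BRESLAUER_DG <- .fill_symmetric(c(
  AA = -1.9, AT = -1.5, TA = -0.9, CA = -1.9, GT = -1.3,
  CT = -1.6, GA = -1.6, CG = -3.6, GC = -3.1, GG = -3.1))

.GAS_CONSTANT <- 1.987 # cal / (mol K)

#' Thermodynamic parameter set for primer evaluation
#'
#' Bundles the nearest-neighbor table choice and solution conditions used by
#' [tm_nn()], [dg_3prime_end()] and the binding-site search.
#'
#' @param nn_table Stack parameter set for the 3'-end free-energy rule:
#'   `"breslauer_1986"` (default) or `"unified_1998"`.  Melting temperatures
#'   always use the unified dH/dS set, which is the standard choice for
#'   primer Tm prediction.
#' @param monovalent_mM Monovalent cation concentration in mM (default 50).
#' @param primer_conc_nM Total primer strand concentration in nM (default 250).
#' @return An object of class `thermo_params`.
#' @examples
#' tp <- thermo_params()
#' tm_nn("ACGTACGTACGTACGTACGT", tp)
#' @export
thermo_params <- function(nn_table = c("breslauer_1986", "unified_1998"),
                          monovalent_mM = 50, primer_conc_nM = 250) {
  nn_table <- match.arg(nn_table)
  if (monovalent_mM <= 0 || primer_conc_nM <= 0)
    stop("concentrations must be positive")
  structure(list(nn_table_id = nn_table,
                 monovalent_mM = monovalent_mM,
                 primer_conc_nM = primer_conc_nM),
            class = "thermo_params")
}

.check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop(what, " must be a single character string")
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop(what, " contains characters outside {A,C,G,T}")
  seq
}

.stack_ids <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste0(b[-length(b)], b[-1])
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Computes the duplex melting temperature of a primer against its perfect
#' complement using the unified nearest-neighbor dH/dS parameters with
#' terminal initiation terms, the entropy salt correction
#' `dS + 0.368 (n-1) ln[Na+]`, and the two-state formula
#' `Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15` for non-self-complementary
#' oligos.
#'
#' @param sequence Primer sequence, 5'->3', `A/C/G/T` only, length >= 8.
#' @param thermo A [thermo_params()] object.
#' @return Melting temperature in degrees Celsius.
#' @export
tm_nn <- function(sequence, thermo = thermo_params()) {
  sequence <- .check_dna(sequence, "primer")
  n <- nchar(sequence)
  if (n < 8) stop("primer must be at least 8 nt for a meaningful duplex Tm")
  ids <- .stack_ids(sequence)
  dH <- sum(.NN_UNIFIED_DH[ids])
  dS <- sum(.NN_UNIFIED_DS[ids])
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (term in b[c(1L, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(thermo$monovalent_mM / 1000)
  ct <- thermo$primer_conc_nM * 1e-9
  dH * 1000 / (dS + .GAS_CONSTANT * log(ct / 4)) - 273.15
}

#' Stability of a primer's 3'-terminal pentamer
#'
#' Sums the four nearest-neighbor stack free energies over the last five
#' residues of a primer.  Pairs whose 3' pentamer is more stable than
#' -9 kcal/mol are prone to massive nonspecific priming and are discarded
#' outright by the scoring rules (see [score_clone()]).
#'
#' @inheritParams tm_nn
#' @param primer Primer sequence, 5'->3', length >= 5.
#' @return Free energy in kcal/mol (negative for Watson-Crick stacks).
#' @export
dg_3prime_end <- function(primer, thermo = thermo_params()) {
  primer <- .check_dna(primer, "primer")
  n <- nchar(primer)
  if (n < 5) stop("primer must be at least 5 nt to evaluate the 3' pentamer")
  pent <- substr(primer, n - 4L, n)
  tbl <- switch(thermo$nn_table_id,
                breslauer_1986 = .NN_BRESLAUER_DG,
                unified_1998   = .NN_UNIFIED_DG)
  sum(tbl[.stack_ids(pent)])
}

# Duplex Tm of a primer bound at a site with mismatches: stacks form only
# between adjacent matched positions; mismatched positions contribute no
# dH/dS.  `match` is a logical vector in primer orientation.  Monotone in the
# number of matched positions for a fixed primer.
.duplex_tm <- function(sequence, match, thermo) {
  n <- nchar(sequence)
  ids <- .stack_ids(sequence)
  keep <- match[-n] & match[-1]
  dH <- sum(.NN_UNIFIED_DH[ids[keep]])
  dS <- sum(.NN_UNIFIED_DS[ids[keep]])
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (term in b[c(1L, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(thermo$monovalent_mM / 1000)
  ct <- thermo$primer_conc_nM * 1e-9
  denom <- dS + .GAS_CONSTANT * log(ct / 4)
  if (dH == 0 || denom >= 0) return(-273.15)
  dH * 1000 / denom - 273.15
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (`A/C/G/T/N`).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) .revcomp_chr(toupper(x))
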