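# Virtual 1% agarose gel electrophoresis.  Band mobility follows the
# empirical semi-log law r(L) = a + b*log10(L + c), scaled through the
# migration of a known marker band (default: the 2000 bp fragment of a
# DL2000-style ladder run to 50 mm).  Only *differences* of mobilities feed
# any decision, via the minimum eye-resolvable distance m_min.

#' Virtual gel configuration
#'
#' @param a,b,c Empirical mobility constants (defaults 4.61, -0.72, 474.65,
#'   calibrated for 1% agarose).
#' @param marker_size_bp Size of the calibration marker band (default 2000).
#' @param marker_migration_mm Observed migration of the marker band in mm
#'   (default 50, a typical minigel run).
#' @param m_min_mm Minimum distance between two bands distinguishable by eye,
#'   in mm (default 2).
#' @return An object of class `gel_config`.
#' @export
gel_config <- function(a = 4.61, b = -0.72, c = 474.65,
                       marker_size_bp = 2000, marker_migration_mm = 50,
                       m_min_mm = 2) {
  if (m_min_mm <= 0) stop("m_min_mm must be positive")
  if (marker_migration_mm <= 0) stop("marker_migration_mm must be positive")
  cfg <- structure(list(a = a, b = b, c = c, marker_size_bp = marker_size_bp,
                        marker_migration_mm = marker_migration_mm,
                        m_min_mm = m_min_mm), class = "gel_config")
  # the relative-mobility law must stay positive across the amplicon range
  r <- .gel_r(c(50, 10000, marker_size_bp), cfg)
  if (any(r <= 0))
    stop("gel config error: mobility law non-positive over 50..10000 bp")
  cfg
}

.gel_r <- function(size_bp, cfg) cfg$a + cfg$b * log10(size_bp + cfg$c)

#' Predicted migration of a DNA fragment
#'
#' `mobility(L) = marker_migration_mm * r(L) / r(marker_size_bp)` with
#' `r(L) = a + b log10(L + c)`; strictly decreasing in fragment size.
#'
#' @param size_bp Fragment size(s) in bp, >= 1 (vectorized).
#' @param cfg A [gel_config()].
#' @return Migration distance(s) in mm.
#' @examples
#' mobility(2000) # exactly the marker migration, 50 mm
#' @export
mobility <- function(size_bp, cfg = gel_config()) {
  if (any(size_bp <= 0)) stop("fragment size must be positive")
  cfg$marker_migration_mm * .gel_r(size_bp, cfg) / .gel_r(cfg$marker_size_bp, cfg)
}

#' Distance between two bands on the virtual gel
#'
#' @param size_i,size_j Fragment sizes in bp.
#' @inheritParams mobility
#' @return `abs(mobility(size_i) - mobility(size_j))` in mm.
#' @export
migration_distance <- function(size_i, size_j, cfg = gel_config()) {
  abs(mobility(size_i, cfg) - mobility(size_j, cfg))
}

#' Partition amplicons into co-migrating band groups
#'
#' Two amplicons co-migrate when their predicted bands are closer than
#' `m_min_mm`; groups are the connected components of this relation
#' (single-linkage), so a chain of pairwise-indistinguishable bands forms one
#' group.  Singleton groups are visually resolvable bands.
#'
#' @param sizes Integer vector of amplicon sizes in bp.
#' @inheritParams mobility
#' @return An integer vector of group ids (1-based), parallel to `sizes`;
#'   group ids are assigned in order of first appearance.
#' @export
comigrating_groups <- function(sizes, cfg = gel_config()) {
  n <- length(sizes)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mob <- mobility(sizes, cfg)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (abs(mob[i] - mob[j]) < cfg$m_min_mm) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
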