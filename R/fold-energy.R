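# Nearest-neighbor energy model for hairpin-class RNA secondary structure.
#
# The model scores structures in which the base pairs form a single nested
# chain (one stem-loop, possibly interrupted by bulges and internal loops;
# no multiloops, no pseudoknots). This is the structure class of miRNA
# precursor candidates, and it keeps exhaustive enumeration tractable so the
# dynamic program can be verified against a brute-force oracle on short
# sequences.
#
# Energy terms (kcal/mol):
#   * Watson-Crick + GU wobble pairs only.
#   * Stacking energies for adjacent pairs from the 6x6 table below
#     (Turner-style magnitudes).
#   * Hairpin loop of n unpaired bases (n >= 3): 5.4 + 1.08 * log(n / 3).
#   * Bulge of n bases (one side of a helix interruption empty, n >= 1):
#     3.8 + 1.08 * log(n); no stacking bonus across a bulge.
#   * Internal loop with a and b unpaired bases (both >= 1):
#     4.0 + 1.08 * log((a + b) / 2) + min(3, 0.5 * |a - b|).
#   * No dangling ends, terminal AU penalties or special tetraloops.
# The empty structure has energy 0; the reported minimum free energy is
# never positive.

PAIR_CODES <- c("AT", "TA", "CG", "GC", "GT", "TG")

# pair type index, 0 = not pairable
pair_type <- function(b1, b2) {
  m <- match(paste0(b1, b2), PAIR_CODES)
  ifelse(is.na(m), 0L, m)
}

# stacking energy: rows = outer (closing) pair 5'->3', cols = inner pair
STACK_TABLE <- matrix(c(
  # inner:  AT     TA     CG     GC     GT     TG
  -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,  # outer AT
  -1.33, -0.93, -2.35, -2.11, -1.27, -1.00,  # outer TA
  -2.11, -2.08, -3.26, -2.36, -1.41, -2.11,  # outer CG
  -2.35, -2.24, -3.42, -3.26, -2.51, -1.53,  # outer GC
  -1.27, -1.00, -2.11, -1.53, -0.50, -0.30,  # outer GT
  -0.55, -1.36, -1.41, -2.51, -0.30, -0.50   # outer TG
), nrow = 6, byrow = TRUE, dimnames = list(PAIR_CODES, PAIR_CODES))

MIN_HAIRPIN_LOOP <- 3L   # minimum unpaired bases closed by a pair
MAX_LOOP_SIDE <- 30L     # max unpaired bases on one side of an interruption

hairpin_penalty <- function(n) {
  ifelse(n < MIN_HAIRPIN_LOOP, Inf, 5.4 + 1.08 * log(n / 3))
}

bulge_penalty <- function(n) 3.8 + 1.08 * log(n)

internal_penalty <- function(a, b) {
  4.0 + 1.08 * log((a + b) / 2) + pmin(3, 0.5 * abs(a - b))
}

# transition energy between consecutive chain pairs (i,j) > (c,d), with
# a = c-i-1 and b = j-d-1 unpaired bases on the two sides
transition_energy <- function(outer_pt, inner_pt, a, b) {
  if (a == 0L && b == 0L) return(STACK_TABLE[outer_pt, inner_pt])
  if (a == 0L || b == 0L) return(bulge_penalty(a + b))
  internal_penalty(a, b)
}

seq_to_int <- function(sequence) {
  v <- match(strsplit(as_dna(sequence), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  if (anyNA(v)) stop("sequence contains characters outside ACGU/T")
  v - 1L
}

#' Score a hairpin-class structure under the package energy model
#'
#' Computes the free energy of an explicit nested chain of base pairs, the
#' same arithmetic the folding dynamic program optimises. Used as an
#' internal consistency route: the energy of the structure returned by
#' [fold()] re-scored here equals the reported minimum free energy.
#'
#' @param sequence nucleotide string (ACGU/T).
#' @param pairs two-column integer matrix of 1-based pair coordinates
#'   (5' position, 3' position), strictly nested from outermost to
#'   innermost. A zero-row matrix scores 0.
#' @return free energy in kcal/mol.
#' @export
structure_energy <- function(sequence, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(0)
  s <- strsplit(as_dna(sequence), "", fixed = TRUE)[[1]]
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  pt <- vapply(seq_len(nrow(pairs)), function(r) {
    pair_type(s[pairs[r, 1L]], s[pairs[r, 2L]])
  }, integer(1))
  if (any(pt == 0L)) stop("structure contains a non-canonical pair")
  e <- 0
  for (r in seq_len(nrow(pairs) - 1L)) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    c <- pairs[r + 1L, 1L]; d <- pairs[r + 1L, 2L]
    if (!(i < c && c < d && d < j)) stop("pairs are not strictly nested")
    e <- e + transition_energy(pt[r], pt[r + 1L], c - i - 1L, j - d - 1L)
  }
  inner <- pairs[nrow(pairs), ]
  unname(e + hairpin_penalty(inner[2L] - inner[1L] - 1L))
}

# energy parameter bundle handed to the C++ dynamic program; penalties are
# precomputed in R so both routes share identical floating-point values
fold_energy_params <- function(n) {
  loop_sizes <- seq_len(max(n, 1L))
  list(
    stack = STACK_TABLE,
    hairpin = vapply(loop_sizes, hairpin_penalty, numeric(1)),
    bulge = vapply(loop_sizes, bulge_penalty, numeric(1)),
    internal = outer(loop_sizes, loop_sizes, internal_penalty),
    min_hairpin = MIN_HAIRPIN_LOOP,
    max_loop_side = MAX_LOOP_SIDE
  )
}
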