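#' Fold a sequence into its minimum-free-energy hairpin structure
#'
#' Computes the minimum-free-energy secondary structure over the
#' hairpin-class structure space (a single nested chain of canonical
#' Watson-Crick / GU pairs: one stem-loop with bulges and internal loops,
#' no multiloops or pseudoknots) under the package's nearest-neighbor
#' energy model. This is the structure class relevant to miRNA precursor
#' candidates. If no structure has negative free energy the empty structure
#' is returned with `delta_g = 0`.
#'
#' @param sequence nucleotide string, alphabet ACGU (T accepted), length
#'   5-500 nt.
#' @return an object of class `fold_result`: list with `sequence` (as
#'   given), `structure` (dot-bracket string, same length), `delta_g`
#'   (kcal/mol, <= 0), and `pairs` (integer vector; `pairs[i]` is the
#'   1-based partner of position i, `NA` if unpaired).
#' @examples
#' fold("GGGGCCCCAAAAGGGGCCCC")
#' @export
fold <- function(sequence) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 5L || n > 500L) {
    stop("fold() accepts sequences of 5-500 nt, got ", n)
  }
  si <- seq_to_int(sequence)   # errors on invalid alphabet
  par <- fold_energy_params(n)
  res <- fold_mfe_cpp(si, par$stack, par$hairpin, par$bulge, par$internal,
                      par$min_hairpin, par$max_loop_side)
  pairs <- res$pairs
  pv <- rep(NA_integer_, n)
  db <- rep(".", n)
  if (nrow(pairs) > 0L) {
    pv[pairs[, 1L]] <- pairs[, 2L]
    pv[pairs[, 2L]] <- pairs[, 1L]
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  structure(
    list(sequence = sequence,
         structure = paste(db, collapse = ""),
         delta_g = res$energy,
         pairs = pv),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "  (", sprintf("%.2f", x$delta_g),
      " kcal/mol)\n", sep = "")
  invisible(x)
}

# pair matrix (outermost first) from a fold_result, for re-scoring
fold_pairs_matrix <- function(fr) {
  idx <- which(!is.na(fr$pairs) & seq_along(fr$pairs) < fr$pairs)
  if (length(idx) == 0L) return(matrix(integer(0), ncol = 2))
  m <- cbind(idx, fr$pairs[idx])
  m[order(m[, 1L]), , drop = FALSE]
}
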