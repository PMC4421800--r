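# Seed-match target-site scanning of 3'UTRs.
#
# Canonical site types, defined by complementarity to the miRNA 5' end
# (positions counted 1-based from the miRNA 5' end):
#   8mer    : perfect match to positions 2-8, plus an A opposite position 1
#   7mer-m8 : perfect match to positions 2-8
#   7mer-A1 : perfect match to positions 2-7, plus an A opposite position 1
#   6mer    : perfect match to positions 2-7
# Each UTR window is reported once, with its most stringent type.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Scan a 3'UTR for miRNA seed-match sites
#'
#' Finds all seed matches of a mature miRNA in a UTR and types each site.
#' The site sequence on the UTR is the reverse complement of the required
#' miRNA positions; the "A" of A1-type sites is an adenosine in the UTR
#' opposite miRNA position 1, regardless of complementarity.
#'
#' @param utr UTR sequence (DNA or RNA).
#' @param mature mature miRNA sequence, at least 8 nt.
#' @param utr_id,mirna_id identifiers copied into the output.
#' @return data.frame of sites ordered by position: `utr_id`, `mirna_id`,
#'   `start`, `end` (1-based inclusive span of the seed match plus the A1
#'   position where applicable), `type`, `site_seq`. 0-based half-open
#'   coordinates are in `start0`/`end0`. UTRs shorter than 7 nt give an
#'   empty list.
#' @export
scan_seed_sites <- function(utr, mature, utr_id = "utr",
                            mirna_id = "mirna") {
  empty <- data.frame(utr_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0),
                      type = character(0), site_seq = character(0),
                      start0 = integer(0), end0 = integer(0),
                      stringsAsFactors = FALSE)
  utr <- as_dna(utr); mature <- as_dna(mature)
  if (nchar(mature) < 8L) stop("mature miRNA must be at least 8 nt")
  if (nchar(utr) < 7L) return(empty)
  m6 <- revcomp(substr(mature, 2L, 7L))   # 6mer site core
  m7 <- revcomp(substr(mature, 2L, 8L))   # 7mer-m8 site core
  uv <- strsplit(utr, "", fixed = TRUE)[[1]]
  L <- nchar(utr)
  rows <- list()
  # slide over all windows where the 6mer core fits
  for (s in seq_len(L - 6L + 1L)) {          # 1-based core start
    core6 <- substr(utr, s, s + 5L)
    if (core6 != m6) next
    has_m8 <- s >= 2L && substr(utr, s - 1L, s + 5L) == m7
    # position opposite miRNA position 1 is immediately 3' of the core
    has_a1 <- s + 6L <= L && uv[s + 6L] == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    st <- if (has_m8) s - 1L else s
    en <- if (has_a1) s + 6L else s + 5L
    rows[[length(rows) + 1L]] <- data.frame(
      utr_id = utr_id, mirna_id = mirna_id, start = st, end = en,
      type = type, site_seq = substr(utr, st, en),
      start0 = st - 1L, end0 = en, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Scan many UTRs against many miRNAs
#'
#' @param utrs,matures named character vectors.
#' @return combined site table from [scan_seed_sites()].
#' @export
scan_all_targets <- function(utrs, matures) {
  res <- list()
  for (u in names(utrs)) {
    for (m in names(matures)) {
      s <- scan_seed_sites(utrs[[u]], matures[[m]], utr_id = u,
                           mirna_id = m)
      if (nrow(s) > 0) res[[length(res) + 1L]] <- s
    }
  }
  if (length(res) == 0L) {
    return(scan_seed_sites(strrep("C", 10), strrep("A", 22)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Conservation of a seed site across an aligned UTR block
#'
#' Maps the reference-row site through the alignment columns and checks,
#' per species, whether the ungapped sequence at those columns is an
#' identical seed match.
#'
#' @param aligned named character vector of aligned UTRs (equal length;
#'   gaps `-`).
#' @param site one row of [scan_seed_sites()] output, with coordinates on
#'   the ungapped reference row.
#' @param reference name of the reference row.
#' @param clades optional named list grouping species for per-clade
#'   conserved fractions.
#' @return list with `presence` (named logical per species),
#'   `conserved_fraction` (over non-reference rows), and `per_clade`
#'   (named fractions, if `clades` given).
#' @export
site_conservation <- function(aligned, site, reference, clades = NULL) {
  stopifnot(reference %in% names(aligned))
  ref <- strsplit(as_dna(aligned[[reference]]), "", fixed = TRUE)[[1]]
  unc <- which(ref != "-")           # alignment column of each ungapped pos
  if (site$end > length(unc)) stop("site outside the ungapped reference")
  cols <- unc[site$start:site$end]
  if (length(cols) == 0L || all(ref[cols] == "-")) {
    stop("site overlaps an all-gap region in the reference")
  }
  target <- paste(ref[cols], collapse = "")
  presence <- vapply(names(aligned), function(sp) {
    row <- strsplit(as_dna(aligned[[sp]]), "", fixed = TRUE)[[1]]
    paste(row[cols], collapse = "") == target
  }, logical(1))
  others <- setdiff(names(aligned), reference)
  out <- list(presence = presence,
              conserved_fraction = mean(presence[others]))
  if (!is.null(clades)) {
    out$per_clade <- vapply(clades, function(sp) {
      mean(presence[intersect(sp, names(presence))])
    }, numeric(1))
  }
  out
}

#' Write seed sites as BED (0-based half-open)
#'
#' @param sites site table from [scan_seed_sites()].
#' @param path output BED file.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$utr_id, sites$start0, sites$end0,
                    paste(sites$mirna_id, sites$type, sep = "|"))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
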