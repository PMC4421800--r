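# Raw-read cleanup and tag collapsing.
#
# Raw small-RNA reads are a fixed-width sequencer output: the insert
# followed by the 3' adapter (and filler). Cleanup removes, in a fixed
# rule order, low-quality reads, reads contaminated by the 5' adapter,
# reads with no detectable 3' adapter, inserts longer than the configured
# ceiling ("inserted fragments"), poly(A) stretches, and inserts shorter
# than the floor.

DISCARD_RULES <- c("low_quality", "adapter5_contamination",
                   "adapter3_missing", "inserted_fragment",
                   "poly_a", "too_short")

#' Filter raw reads and trim the 3' adapter
#'
#' Applies the cleanup rules in a fixed order and reports a per-rule
#' discard tally. The 3' adapter is detected as the first occurrence of an
#' adapter prefix of at least `adapter_min_overlap` nt with at most one
#' mismatch; the insert is everything before it.
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (Sanger/Phred+33), as produced by [read_fastq()] or
#'   [simulate_libraries()].
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 5' adapter sequence; reads whose sequence starts with
#'   its first `adapter_min_overlap` bases are discarded as contamination.
#' @param min_len,max_len insert length bounds (defaults 18 and 32 nt).
#' @param quality_floor minimum mean Phred score (default 20); reads
#'   without qualities are not quality-filtered.
#' @param polya_frac inserts with at least this fraction of A are
#'   discarded as poly(A) stretches (default 0.8).
#' @param adapter_min_overlap minimum adapter prefix length for detection
#'   (default 6).
#' @return list with `clean` (data.frame id, insert, length) and `tally`
#'   (named integer vector over the discard rules, in fixed order, plus
#'   `clean`).
#' @export
filter_and_trim <- function(reads, adapter3, adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            min_len = 18L, max_len = 32L,
                            quality_floor = 20, polya_frac = 0.8,
                            adapter_min_overlap = 6L) {
  stopifnot(nzchar(adapter3), nzchar(adapter5), min_len >= 1L)
  if (!all(c("id", "seq") %in% names(reads))) {
    stop("reads must have 'id' and 'seq' columns")
  }
  bad <- which(is.na(reads$seq) | !nzchar(reads$seq))
  if (length(bad) > 0) {
    stop("malformed read record at index ", bad[1L])
  }
  seqs <- as_dna(reads$seq)
  n <- length(seqs)
  tally <- setNames(integer(length(DISCARD_RULES)), DISCARD_RULES)
  keep <- rep(TRUE, n)
  discard <- function(idx, rule) {
    idx <- idx[keep[idx]]
    tally[rule] <<- tally[rule] + length(idx)
    keep[idx] <<- FALSE
  }

  # 1. quality floor (mean Phred)
  if ("qual" %in% names(reads) && !all(is.na(reads$qual))) {
    mq <- vapply(reads$qual, function(q) {
      if (is.na(q) || !nzchar(q)) return(Inf)
      mean(utf8ToInt(q) - 33L)
    }, numeric(1), USE.NAMES = FALSE)
    discard(which(mq < quality_floor), "low_quality")
  }

  # 2. 5' adapter contamination: read starts with the 5' adapter prefix
  a5 <- substr(as_dna(adapter5), 1L, adapter_min_overlap)
  discard(which(keep & startsWith(seqs, a5)), "adapter5_contamination")

  # 3. locate the 3' adapter; no hit -> discard
  apos <- find_adapter3(seqs, as_dna(adapter3), adapter_min_overlap)
  discard(which(keep & apos < 0L), "adapter3_missing")

  inserts <- substr(seqs, 1L, pmax(apos, 0L))
  len <- nchar(inserts)

  # 4. inserted fragments (insert longer than the ceiling)
  discard(which(keep & len > max_len), "inserted_fragment")

  # 5. poly(A) stretches
  n_a <- nchar(gsub("[^A]", "", inserts))
  discard(which(keep & len > 0L & n_a / pmax(len, 1L) >= polya_frac),
          "poly_a")

  # 6. too short
  discard(which(keep & len < min_len), "too_short")

  clean <- data.frame(id = reads$id[keep], insert = inserts[keep],
                      length = len[keep], stringsAsFactors = FALSE)
  rownames(clean) <- NULL
  list(clean = clean, tally = c(tally, clean = nrow(clean)))
}

# First position (0-based insert length) at which the adapter starts.
# Detection prefers the longest adapter prefix: a fast exact search for a
# 12 nt prefix first, then a per-read scan for the longest prefix of
# >= min_overlap nt with <= 1 mismatch. -1 if absent.
find_adapter3 <- function(seqs, adapter3, min_overlap) {
  probe_len <- min(12L, nchar(adapter3))
  probe <- substr(adapter3, 1L, probe_len)
  pos <- as.integer(regexpr(probe, seqs, fixed = TRUE)) - 1L
  miss <- which(pos < 0L)
  if (length(miss) > 0) {
    av <- strsplit(adapter3, "", fixed = TRUE)[[1]]
    pos[miss] <- vapply(seqs[miss], function(s) {
      L <- nchar(s)
      if (L < min_overlap) return(-1L)
      sv <- strsplit(s, "", fixed = TRUE)[[1]]
      for (plen in seq(min(length(av), L), min_overlap)) {
        pv <- av[seq_len(plen)]
        for (st in 0:(L - plen)) {
          if (sum(sv[(st + 1):(st + plen)] != pv) <= 1L) return(st)
        }
      }
      -1L
    }, integer(1), USE.NAMES = FALSE)
  }
  pos
}

#' Collapse clean inserts into unique sequence tags
#'
#' One tag per distinct sequence, with per-stage read counts. Stage counts
#' are conserved: for every stage the tag counts sum to the number of
#' clean inserts in that stage.
#'
#' @param inserts_by_stage named list (stage -> character vector of clean
#'   insert sequences).
#' @return data.frame with `tag_id`, `seq`, `length`, one count column per
#'   stage, and `total_count`; ordered by decreasing total count then
#'   sequence.
#' @export
collapse_tags <- function(inserts_by_stage) {
  stages <- names(inserts_by_stage)
  if (is.null(stages) || any(!nzchar(stages))) {
    stop("inserts_by_stage must be a named list")
  }
  all_seqs <- sort(unique(unlist(lapply(inserts_by_stage, as_dna),
                                 use.names = FALSE)))
  counts <- vapply(stages, function(s) {
    t <- table(factor(as_dna(inserts_by_stage[[s]]), levels = all_seqs))
    as.integer(t)
  }, integer(length(all_seqs)))
  if (length(all_seqs) == 1L) counts <- matrix(counts, nrow = 1L)
  colnames(counts) <- stages
  total <- rowSums(counts)
  ord <- order(-total, all_seqs)
  out <- data.frame(tag_id = sprintf("tag_%05d", seq_along(all_seqs)),
                    seq = all_seqs[ord], length = nchar(all_seqs[ord]),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts[ord, , drop = FALSE]))
  out$total_count <- total[ord]
  rownames(out) <- NULL
  out
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file.
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write collapsed tags as FASTA with count headers and a count matrix
#'
#' Headers follow the `tag_<id>_x<count>` convention.
#'
#' @param tags collapsed tag table from [collapse_tags()].
#' @param fasta_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_tags <- function(tags, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    seqs <- setNames(tags$seq,
                     sprintf("%s_x%d", tags$tag_id, tags$total_count))
    write_fasta(seqs, fasta_path)
  }
  if (!is.null(tsv_path)) write_tsv(tags, tsv_path)
  invisible(tags)
}
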