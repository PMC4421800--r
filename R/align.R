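#' Build an ungapped mapping index over a set of reference sequences
#'
#' Prepares the reference set for [map_tag()]. Lookup is exact-seed based
#' (seed length `k`) with full verification by Hamming distance on both
#' strands; verification is delegated to Biostrings' mismatch-tolerant
#' pattern matching.
#'
#' @param references named character vector of reference sequences (DNA or
#'   RNA; U is converted to T).
#' @param k seed length (default 12). Must not exceed the shortest tag that
#'   will be mapped.
#' @return an object of class `seed_index`.
#' @export
build_index <- function(references, k = 12L) {
  if (length(references) == 0L) stop("empty reference set")
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    stop("references must be named")
  }
  chars <- as_dna(references)
  refs <- Biostrings::DNAStringSet(chars)
  names(refs) <- names(references)
  structure(list(refs = refs, chars = chars,
                 ints = lapply(chars, encode_bases),
                 k = as.integer(k)),
            class = "seed_index")
}

#' Map a tag against an index, reporting all hit loci
#'
#' Ungapped alignment of a short tag against every reference on both
#' strands. A hit is a reference window with Hamming distance at most
#' `max_mismatches` from the tag (reverse complement for the minus strand).
#' Hits are sorted by (mismatches, reference id, start); when more than
#' `max_hits` loci exist the list is truncated and flagged.
#'
#' @param tag sequence string (>= k nt). Tags containing more than 2 `N`
#'   bases are rejected as unmappable.
#' @param index a `seed_index` from [build_index()].
#' @param max_mismatches Hamming budget (0 for genome mapping, up to 2 for
#'   ncRNA reference sets).
#' @param max_hits cap on reported loci (default unlimited).
#' @return data.frame with columns `ref`, `start` (0-based), `end`
#'   (exclusive), `strand`, `mismatches`, and attribute `truncated`
#'   (logical).
#' @export
map_tag <- function(tag, index, max_mismatches = 0L, max_hits = Inf) {
  stopifnot(inherits(index, "seed_index"))
  tag <- as_dna(tag)
  if (lengths(regmatches(tag, gregexpr("N", tag)))[1] > 2L) {
    stop("tag contains more than 2 N bases; unmappable")
  }
  if (nchar(tag) < index$k) stop("tag shorter than seed length k")
  hits <- if (max_mismatches == 0L) {
    map_tag_exact(tag, index$chars)
  } else {
    map_tag_raw(tag, index$ints, max_mismatches)
  }
  hits <- hits[order(hits$mismatches, hits$ref, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  truncated <- nrow(hits) > max_hits
  n_total <- nrow(hits)
  if (truncated) hits <- hits[seq_len(max_hits), , drop = FALSE]
  attr(hits, "truncated") <- truncated
  attr(hits, "n_total") <- n_total
  hits
}

# exact matching via fixed-string search on both strands (fast path)
map_tag_exact <- function(tag, chars) {
  rc <- revcomp(tag)
  w <- nchar(tag)
  out <- list()
  for (rid in names(chars)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") tag else rc
      m <- gregexpr(pat, chars[[rid]], fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      # overlapping occurrences: rescan from inside each match
      starts <- integer(0)
      p <- 1L
      while (TRUE) {
        hit <- regexpr(pat, substr(chars[[rid]], p, nchar(chars[[rid]])),
                       fixed = TRUE)
        if (hit == -1L) break
        starts <- c(starts, p + as.integer(hit) - 1L)
        p <- p + as.integer(hit)
      }
      out[[length(out) + 1L]] <- data.frame(
        ref = rid, start = starts - 1L, end = starts - 1L + w,
        strand = str, mismatches = 0L, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ref = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# base encoding for the Hamming scanner: ACGT -> 0..3, anything else
# (N) -> 4, which mismatches every reference base
encode_bases <- function(x) {
  v <- match(strsplit(as_dna(x), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v - 1L
}

# mismatch-tolerant mapping: full Hamming verification on both strands
map_tag_raw <- function(tag, ref_ints, max_mismatches) {
  pat_fwd <- encode_bases(tag)
  pat_rev <- encode_bases(revcomp(tag))
  w <- length(pat_fwd)
  out <- list()
  for (rid in names(ref_ints)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") pat_fwd else pat_rev
      m <- hamming_scan_cpp(pat, ref_ints[[rid]], max_mismatches)
      if (nrow(m) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        ref = rid, start = m[, 1L], end = m[, 1L] + w, strand = str,
        mismatches = m[, 2L], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ref = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Map a set of tags, returning one combined hit table
#'
#' @param tags named character vector (names are tag ids).
#' @inheritParams map_tag
#' @return data.frame as [map_tag()] plus a `tag_id` column; tags with more
#'   than 2 N bases are skipped (no hits).
#' @export
map_tags <- function(tags, index, max_mismatches = 0L, max_hits = Inf) {
  acc <- list(tag_id = character(0), ref = character(0),
              start = integer(0), end = integer(0),
              strand = character(0), mismatches = integer(0),
              truncated = logical(0))
  for (id in names(tags)) {
    h <- tryCatch(map_tag(tags[[id]], index, max_mismatches, max_hits),
                  error = function(e) NULL)
    if (is.null(h) || nrow(h) == 0L) next
    acc$tag_id <- c(acc$tag_id, rep(id, nrow(h)))
    acc$ref <- c(acc$ref, h$ref)
    acc$start <- c(acc$start, h$start)
    acc$end <- c(acc$end, h$end)
    acc$strand <- c(acc$strand, h$strand)
    acc$mismatches <- c(acc$mismatches, h$mismatches)
    acc$truncated <- c(acc$truncated, rep(attr(h, "truncated"), nrow(h)))
  }
  as.data.frame(acc, stringsAsFactors = FALSE)
}
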