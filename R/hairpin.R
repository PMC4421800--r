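# Novel miRNA discovery: candidate windows around unannotated tag loci are
# folded under the hairpin-class energy model and screened against the
# discovery criteria, with per-criterion rejection reasons.

#' Discovery parameter set for novel miRNA prediction
#'
#' Defaults are the standard stringent thresholds for hairpin-based
#' discovery from deeply sequenced small-RNA libraries: mature length
#' 18-26 nt, cutting-site depth at least 3 reads, at most 20 genomic
#' copies, precursor free energy at most -18 kcal/mol, at most 35 nt
#' between the mature and star arms, at least 14 duplex base pairs, bulges
#' of at most 4 nt and duplex asymmetry of at most 5 nt; a 10 nt flank is
#' retained around the stem when trimming the precursor, and candidate
#' windows extend 100 nt on either side of the tag locus.
#'
#' @param mature_len length bounds of the mature product, nt.
#' @param min_cut_depth minimum read depth at the modal 5' cutting site.
#' @param max_copies maximum number of genomic hit loci for the mature tag.
#' @param max_free_energy maximum (least negative) precursor free energy,
#'   kcal/mol.
#' @param max_loop_space maximum bases between the mature and star arms.
#' @param min_duplex_pairs minimum base pairs joining the two arms.
#' @param max_bulge maximum run of consecutive unpaired bases inside the
#'   duplex on either arm.
#' @param max_asymmetry maximum difference between unpaired counts on the
#'   two arms within the duplex.
#' @param precursor_flank margin kept around the arms when trimming the
#'   precursor, nt.
#' @param search_flank genomic window extension around a tag locus, nt.
#' @return object of class `discovery_params`.
#' @export
discovery_params <- function(mature_len = c(18L, 26L), min_cut_depth = 3L,
                             max_copies = 20L, max_free_energy = -18,
                             max_loop_space = 35L, min_duplex_pairs = 14L,
                             max_bulge = 4L, max_asymmetry = 5L,
                             precursor_flank = 10L, search_flank = 100L) {
  structure(list(mature_len = as.integer(mature_len),
                 min_cut_depth = as.integer(min_cut_depth),
                 max_copies = as.integer(max_copies),
                 max_free_energy = max_free_energy,
                 max_loop_space = as.integer(max_loop_space),
                 min_duplex_pairs = as.integer(min_duplex_pairs),
                 max_bulge = as.integer(max_bulge),
                 max_asymmetry = as.integer(max_asymmetry),
                 precursor_flank = as.integer(precursor_flank),
                 search_flank = as.integer(search_flank)),
            class = "discovery_params")
}

#' Extract candidate genomic windows around tag hit loci
#'
#' One window per hit locus, extended by `flank` on both sides and clipped
#' at contig edges. For minus-strand hits the window sequence is
#' reverse-complemented and the tag offset recomputed on that strand.
#'
#' @param hits hit table as from [map_tag()]/[map_tags()] (columns ref,
#'   start, end, strand).
#' @param genome named character vector of contig sequences.
#' @param flank window extension, nt (default 100).
#' @return data.frame with window coordinates (`win_start`, `win_end`,
#'   0-based half-open on the plus strand), `strand`, `window` sequence
#'   (strand-oriented) and `tag_offset` (0-based position of the tag in
#'   the oriented window).
#' @export
extract_candidate_windows <- function(hits, genome, flank = 100L) {
  if (nrow(hits) == 0L) {
    return(cbind(hits[, c("ref", "start", "end", "strand")],
                 win_start = integer(0), win_end = integer(0),
                 window = character(0), tag_offset = integer(0)))
  }
  clen <- nchar(genome)[hits$ref]
  ws <- pmax(0L, hits$start - flank)
  we <- pmin(as.integer(clen), hits$end + flank)
  win <- substr(genome[hits$ref], ws + 1L, we)
  off <- hits$start - ws
  minus <- hits$strand == "-"
  if (any(minus)) {
    win[minus] <- revcomp(win[minus])
    off[minus] <- we[minus] - hits$end[minus]
  }
  out <- data.frame(ref = hits$ref, start = hits$start, end = hits$end,
                    strand = hits$strand, win_start = ws, win_end = we,
                    window = unname(win), tag_offset = unname(off),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Duplex metrics between a mature and a star arm
#'
#' Computed from an explicit secondary structure: `pairs` counts base
#' pairs joining the two arms, `bulge` is the longest run of consecutive
#' unpaired bases inside the duplex on either arm, `asymmetry` the
#' absolute difference between the arms' unpaired counts within the
#' duplex, and `loop_space` the number of bases strictly between the two
#' arms.
#'
#' @param fr a `fold_result` for the precursor.
#' @param mature,star integer length-2 vectors, 0-based half-open arm
#'   coordinates on the precursor. Arms must not overlap.
#' @return list with `pairs`, `bulge`, `asymmetry`, `loop_space`.
#' @export
evaluate_duplex <- function(fr, mature, star) {
  if (max(mature[1], star[1]) < min(mature[2], star[2])) {
    stop("mature and star arms overlap")
  }
  m_idx <- seq.int(mature[1] + 1L, mature[2])       # 1-based positions
  s_idx <- seq.int(star[1] + 1L, star[2])
  partner <- fr$pairs
  in_star <- !is.na(partner[m_idx]) & partner[m_idx] %in% s_idx
  n_pairs <- sum(in_star)
  if (n_pairs == 0L) {
    return(list(pairs = 0L, bulge = 0L, asymmetry = 0L,
                loop_space = loop_space_between(mature, star)))
  }
  arm_metrics <- function(idx, other_idx) {
    duplex <- !is.na(partner[idx]) & partner[idx] %in% other_idx
    lo <- min(which(duplex)); hi <- max(which(duplex))
    inside <- duplex[lo:hi]
    unpaired <- sum(!inside)
    runs <- rle(!inside)
    bulge <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    c(unpaired = unpaired, bulge = bulge)
  }
  m <- arm_metrics(m_idx, s_idx)
  s <- arm_metrics(s_idx, m_idx)
  list(pairs = as.integer(n_pairs),
       bulge = as.integer(max(m["bulge"], s["bulge"])),
       asymmetry = as.integer(abs(m["unpaired"] - s["unpaired"])),
       loop_space = loop_space_between(mature, star))
}

loop_space_between <- function(mature, star) {
  as.integer(if (mature[2] <= star[1]) star[1] - mature[2]
             else mature[1] - star[2])
}

# Star arm inferred from structure: the span of positions paired with the
# mature arm, extended by the canonical 2 nt 3' overhang on the star's 3'
# side (clipped to the precursor and to not overlap the mature arm).
infer_star_arm <- function(fr, m_start, m_end) {
  m_idx <- seq.int(m_start + 1L, m_end)
  partners <- fr$pairs[m_idx]
  partners <- partners[!is.na(partners) &
                         (fr$pairs[m_idx] < m_start + 1L |
                            fr$pairs[m_idx] > m_end)]
  if (length(partners) == 0L) return(NULL)
  lo <- min(partners) - 1L          # back to 0-based
  hi <- max(partners)
  n <- length(fr$pairs)
  if (lo >= m_end) {                # star is the 3' arm
    hi <- min(hi + 2L, n)
  } else {                          # star is the 5' arm
    hi <- min(hi + 2L, m_start)
  }
  c(lo, hi)
}

#' Evaluate a hairpin candidate against the discovery criteria
#'
#' Accepts iff every criterion holds; otherwise lists each violated
#' criterion by name: `mature_length`, `cut_depth`, `max_copies`,
#' `free_energy`, `max_loop`, `min_pairs`, `max_bulge`, `max_asymmetry`.
#'
#' @param candidate list with `mature_length`, `depth`, `copies`,
#'   `delta_g`, and `duplex` (metrics as from [evaluate_duplex()]).
#' @param params a [discovery_params()].
#' @return list with `accept` (logical) and `reasons` (character vector,
#'   empty when accepted).
#' @export
evaluate_precursor_criteria <- function(candidate, params) {
  reasons <- character(0)
  if (candidate$mature_length < params$mature_len[1] ||
      candidate$mature_length > params$mature_len[2]) {
    reasons <- c(reasons, "mature_length")
  }
  if (candidate$depth < params$min_cut_depth) {
    reasons <- c(reasons, "cut_depth")
  }
  if (candidate$copies > params$max_copies) {
    reasons <- c(reasons, "max_copies")
  }
  if (candidate$delta_g > params$max_free_energy) {
    reasons <- c(reasons, "free_energy")
  }
  d <- candidate$duplex
  if (d$loop_space > params$max_loop_space) reasons <- c(reasons, "max_loop")
  if (d$pairs < params$min_duplex_pairs) reasons <- c(reasons, "min_pairs")
  if (d$bulge > params$max_bulge) reasons <- c(reasons, "max_bulge")
  if (d$asymmetry > params$max_asymmetry) {
    reasons <- c(reasons, "max_asymmetry")
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Discover novel miRNAs from unannotated tags
#'
#' Groups genome-mapped tags into read piles, determines the modal 5'
#' cutting site and its depth, folds the candidate window around each
#' pile, infers the star arm from the structure, trims the precursor to
#' the arms plus flank, and evaluates all discovery criteria. Cheap
#' criteria (mature length, copy number, cutting-site depth) are checked
#' before folding. Candidates sharing a precursor locus are deduplicated
#' (accepted over rejected, then deeper).
#'
#' @param tags tag table (columns `tag_id`, `seq`, `total_count`, and
#'   per-stage counts) restricted to the tags that reached the novel-miRNA
#'   stage of the annotation cascade.
#' @param genome named character vector of contigs.
#' @param index `seed_index` over the genome.
#' @param params a [discovery_params()].
#' @return data.frame, one row per candidate locus: coordinates, precursor
#'   sequence and structure, free energy, mature/star arm coordinates
#'   (precursor-relative, 0-based half-open), arm of origin (`5p`/`3p`),
#'   arms with read support (`5p`/`3p`/`both`), depth, copies, duplex
#'   metrics, `accepted`, and comma-separated rejection `reasons`.
#' @export
discover_novel <- function(tags, genome, index = build_index(genome),
                           params = discovery_params()) {
  empty <- data.frame(
    candidate_id = character(0), ref = character(0), strand = character(0),
    precursor_start = integer(0), precursor_end = integer(0),
    precursor = character(0), structure = character(0),
    delta_g = numeric(0), mature_seq = character(0),
    mature_start = integer(0), mature_end = integer(0),
    star_start = integer(0), star_end = integer(0), arm = character(0),
    arms_with_reads = character(0), depth = integer(0),
    copies = integer(0), pairs = integer(0), bulge = integer(0),
    asymmetry = integer(0), loop_space = integer(0),
    accepted = logical(0), reasons = character(0),
    stringsAsFactors = FALSE)
  if (nrow(tags) == 0L) return(empty)

  hits <- map_tags(setNames(tags$seq, tags$tag_id), index,
                   max_mismatches = 0L)
  if (nrow(hits) == 0L) return(empty)
  copies_by_tag <- table(hits$tag_id)
  hits$count <- tags$total_count[match(hits$tag_id, tags$tag_id)]
  hits$five_prime <- ifelse(hits$strand == "+", hits$start, hits$end - 1L)

  # pile = chain of overlapping tag loci on one contig+strand
  piles <- list()
  for (key in unique(paste(hits$ref, hits$strand))) {
    h <- hits[paste(hits$ref, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(h$start[-1L] >
                                     cummax(h$end[-nrow(h)]))))
    for (g in split(h, grp)) piles[[length(piles) + 1L]] <- g
  }

  rows <- list()
  for (p in piles) {
    ref <- p$ref[1L]; strand <- p$strand[1L]
    depth_by_pos <- tapply(p$count, p$five_prime, sum)
    modal <- names(depth_by_pos)[order(-depth_by_pos,
                                       as.integer(names(depth_by_pos)))][1L]
    depth <- as.integer(depth_by_pos[[modal]])
    at_modal <- p[p$five_prime == as.integer(modal), , drop = FALSE]
    sel <- at_modal[order(-at_modal$count,
                          tags$seq[match(at_modal$tag_id, tags$tag_id)]), ][1L, ]
    mature_seq <- tags$seq[match(sel$tag_id, tags$tag_id)]
    mlen <- nchar(mature_seq)
    copies <- as.integer(copies_by_tag[[sel$tag_id]])

    # structural fields neutralised for the cheap pre-check
    cand <- list(mature_length = mlen, depth = depth, copies = copies,
                 delta_g = -Inf,
                 duplex = list(pairs = 0L, bulge = 0L, asymmetry = 0L,
                               loop_space = 0L))
    pre <- evaluate_precursor_criteria(
      cand, within_params(params, min_duplex_pairs = 0L))
    row <- data.frame(
      candidate_id = NA_character_, ref = ref, strand = strand,
      precursor_start = sel$start, precursor_end = sel$end,
      precursor = NA_character_, structure = NA_character_,
      delta_g = NA_real_, mature_seq = mature_seq,
      mature_start = NA_integer_, mature_end = NA_integer_,
      star_start = NA_integer_, star_end = NA_integer_,
      arm = NA_character_, arms_with_reads = NA_character_,
      depth = depth, copies = copies, pairs = NA_integer_,
      bulge = NA_integer_, asymmetry = NA_integer_,
      loop_space = NA_integer_, accepted = FALSE, reasons = "",
      stringsAsFactors = FALSE)
    if (!pre$accept) {
      # cheap criteria failed: report without folding
      row$reasons <- paste(pre$reasons, collapse = ",")
      rows[[length(rows) + 1L]] <- row
      next
    }

    w <- extract_candidate_windows(
      data.frame(ref = ref, start = sel$start, end = sel$end,
                 strand = strand, stringsAsFactors = FALSE),
      genome, flank = params$search_flank)
    fr <- fold(w$window)
    m0 <- w$tag_offset; m1 <- m0 + mlen
    star <- infer_star_arm(fr, m0, m1)
    if (is.null(star)) {
      row$delta_g <- fr$delta_g
      row$pairs <- 0L; row$bulge <- 0L; row$asymmetry <- 0L
      row$loop_space <- 0L
      row$reasons <- paste(unique(c(
        "min_pairs",
        if (fr$delta_g > params$max_free_energy) "free_energy")),
        collapse = ",")
      rows[[length(rows) + 1L]] <- row
      next
    }

    # trim precursor to arms + flank and re-fold
    p0 <- max(0L, min(m0, star[1]) - params$precursor_flank)
    p1 <- min(nchar(w$window), max(m1, star[2]) + params$precursor_flank)
    precursor <- substr(w$window, p0 + 1L, p1)
    fr2 <- fold(precursor)
    m0p <- m0 - p0; m1p <- m1 - p0
    star2 <- infer_star_arm(fr2, m0p, m1p)
    if (is.null(star2)) star2 <- star - p0
    dup <- evaluate_duplex(fr2, c(m0p, m1p), star2)

    cand$delta_g <- fr2$delta_g
    cand$duplex <- dup
    ev <- evaluate_precursor_criteria(cand, params)

    # precursor genomic coordinates (plus-strand)
    if (strand == "+") {
      g0 <- w$win_start + p0; g1 <- w$win_start + p1
    } else {
      g1 <- w$win_end - p0; g0 <- w$win_end - p1
    }
    row$precursor_start <- g0; row$precursor_end <- g1
    row$precursor <- precursor; row$structure <- fr2$structure
    row$delta_g <- fr2$delta_g
    row$mature_start <- m0p; row$mature_end <- m1p
    row$star_start <- star2[1]; row$star_end <- star2[2]
    row$arm <- if (m0p < star2[1]) "5p" else "3p"
    row$pairs <- dup$pairs; row$bulge <- dup$bulge
    row$asymmetry <- dup$asymmetry; row$loop_space <- dup$loop_space
    row$accepted <- ev$accept
    row$reasons <- paste(ev$reasons, collapse = ",")
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)

  # deduplicate candidates sharing a precursor locus (strand-agnostic):
  # accepted beats rejected, then higher depth
  out <- out[order(out$ref, -as.integer(out$accepted), -out$depth), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  kept_iv <- list()
  for (i in seq_len(nrow(out))) {
    iv <- c(out$precursor_start[i], out$precursor_end[i])
    ref <- out$ref[i]
    dup <- FALSE
    for (kv in kept_iv) {
      if (kv$ref == ref && iv[1] < kv$iv[2] && kv$iv[1] < iv[2]) {
        dup <- TRUE; break
      }
    }
    if (dup) keep[i] <- FALSE else {
      kept_iv[[length(kept_iv) + 1L]] <- list(ref = ref, iv = iv)
    }
  }
  out <- out[keep, , drop = FALSE]

  # arm-of-origin bookkeeping: which arms carry read support
  if (nrow(out) > 0L) {
    out$arms_with_reads <- vapply(seq_len(nrow(out)), function(i) {
      if (!out$accepted[i]) return(out$arm[i])
      g0 <- out$precursor_start[i]; g1 <- out$precursor_end[i]
      h <- hits[hits$ref == out$ref[i] & hits$start < g1 &
                  hits$end > g0, , drop = FALSE]
      if (nrow(h) == 0L) return(out$arm[i])
      # precursor-relative midpoints on the oriented precursor
      mid <- (h$start + h$end) / 2
      rel <- if (out$strand[i] == "+") mid - g0 else g1 - mid
      m_mid <- (out$mature_start[i] + out$mature_end[i]) / 2
      s_mid <- (out$star_start[i] + out$star_end[i]) / 2
      on_mature <- abs(rel - m_mid) < abs(rel - s_mid)
      arms <- unique(ifelse(on_mature, out$arm[i],
                            if (out$arm[i] == "5p") "3p" else "5p"))
      if (length(arms) == 2L) "both" else arms
    }, character(1))
    ord <- order(out$ref, out$precursor_start)
    out <- out[ord, , drop = FALSE]
    out$candidate_id <- sprintf("novel_%03d", seq_len(nrow(out)))
  }
  rownames(out) <- NULL
  out
}

# tweak a discovery_params object
within_params <- function(params, ...) {
  mods <- list(...)
  for (nm in names(mods)) params[[nm]] <- mods[[nm]]
  params
}
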