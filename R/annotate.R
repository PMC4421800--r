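# Fixed-priority annotation cascade: every tag receives exactly one
# small-RNA category. Structural ncRNA matches (<= 2 mismatches against
# the reference sets) are removed before miRNA and piRNA calling, genomic
# context (repeat / exon / intron, sense and antisense) is taken from the
# feature annotation at perfectly matched loci, conserved miRNAs are
# matched against a mature + precursor reference set, and remaining tags
# of the right length and genomic context are piRNA candidates.

#' Default category priority for the annotation cascade
#'
#' Structural ncRNAs are removed first, then conserved miRNAs, then
#' genomic context classes, then novel miRNAs and piRNAs; anything left is
#' unannotated. The order is configurable wherever a cascade is run.
#'
#' @return character vector of categories, highest priority first.
#' @export
default_priority <- function() {
  c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA_conserved", "repeat",
    "exon_sense", "exon_antisense", "intron_sense", "intron_antisense",
    "miRNA_novel", "piRNA", "unannotated")
}

#' Match a tag against a conserved mature miRNA reference set
#'
#' A tag matches a reference mature miRNA when the ungapped overlap is at
#' least 16 nt, there are no mismatches within the reference seed
#' (positions 2-8), at most 2 mismatches outside the seed, and the tag
#' maps perfectly onto the reference's linked precursor. The best match
#' maximises overlap, then minimises mismatches.
#'
#' @param tag tag sequence.
#' @param mature_refs named character vector of mature reference
#'   sequences.
#' @param precursor_refs named character vector of precursor sequences.
#' @param mature_link named character vector mapping mature reference name
#'   to precursor name (defaults to identity names).
#' @param min_overlap minimum tag/reference overlap (default 16 nt).
#' @param max_mismatch_outside_seed default 2.
#' @param seed_positions 1-based positions on the mature reference
#'   treated as seed (default 2:8).
#' @return NULL if no reference passes all rules, else a list with
#'   `mature_id`, `overlap`, `mismatches`, `precursor_id`,
#'   `precursor_offset` (0-based offset of the tag on the precursor).
#' @export
match_conserved_mirna <- function(tag, mature_refs, precursor_refs,
                                  mature_link = setNames(names(mature_refs),
                                                         names(mature_refs)),
                                  min_overlap = 16L,
                                  max_mismatch_outside_seed = 2L,
                                  seed_positions = 2:8) {
  if (length(mature_refs) == 0L) return(NULL)
  missing_link <- setdiff(names(mature_refs), names(mature_link))
  if (length(missing_link) > 0) {
    stop("mature reference without precursor link: ",
         paste(missing_link, collapse = ", "))
  }
  tag <- as_dna(tag)
  tv <- strsplit(tag, "", fixed = TRUE)[[1]]
  lt <- length(tv)
  # perfect precursor mapping is required, so screen references by their
  # linked precursor first (cheap fixed-string search). Mapping is
  # orientation-aware: a tag matching the precursor in either orientation
  # counts as perfectly mapped.
  tag_rc <- revcomp(tag)
  prec_hit <- vapply(precursor_refs, function(p) {
    p <- as_dna(p)
    grepl(tag, p, fixed = TRUE) || grepl(tag_rc, p, fixed = TRUE)
  }, logical(1))
  ok_refs <- names(mature_refs)[mature_link[names(mature_refs)] %in%
                                  names(precursor_refs)[prec_hit]]
  best <- NULL
  for (mid in sort(ok_refs)) {
    mv <- strsplit(as_dna(mature_refs[[mid]]), "", fixed = TRUE)[[1]]
    lm <- length(mv)
    # offset = position of tag start relative to mature start
    for (off in seq.int(-(lt - min_overlap), lm - min_overlap)) {
      lo <- max(1L, 1L + off); hi <- min(lm, lt + off)   # on the reference
      ov <- hi - lo + 1L
      if (ov < min_overlap) next
      ref_piece <- mv[lo:hi]
      tag_piece <- tv[(lo - off):(hi - off)]
      mm_pos <- lo:hi
      mism <- ref_piece != tag_piece
      if (any(mism & mm_pos %in% seed_positions)) next
      n_out <- sum(mism & !(mm_pos %in% seed_positions))
      if (n_out > max_mismatch_outside_seed) next
      pid <- mature_link[[mid]]
      prec <- as_dna(precursor_refs[[pid]])
      poff <- as.integer(regexpr(tag, prec, fixed = TRUE)) - 1L
      if (poff < 0L) {
        poff <- as.integer(regexpr(tag_rc, prec, fixed = TRUE)) - 1L
      }
      if (poff < 0L) next
      cand <- list(mature_id = mid, overlap = ov,
                   mismatches = as.integer(n_out), precursor_id = pid,
                   precursor_offset = poff)
      if (is.null(best) || cand$overlap > best$overlap ||
          (cand$overlap == best$overlap &&
             cand$mismatches < best$mismatches)) {
        best <- cand
      }
    }
  }
  best
}

#' Pick the mature representative among isomiR tags
#'
#' The tag with the highest summed count across stages; ties broken by
#' the lexicographically smaller sequence.
#'
#' @param tags data.frame with `seq` and `total_count` (at least one row).
#' @return the selected row.
#' @export
select_mature_representative <- function(tags) {
  stopifnot(nrow(tags) >= 1L)
  tags[order(-tags$total_count, tags$seq), ][1L, ]
}

#' piRNA call for a single tag
#'
#' A tag is a piRNA candidate iff its length lies within the band
#' (default 24-32 nt) and its genomic loci are intergenic (or
#' repeat-derived unless `require_unannotated`). The 5' base is recorded
#' but not required: the uridine bias is a population property.
#'
#' @param tag_len tag length, nt.
#' @param first_nt 5' base of the tag.
#' @param locus_classes character vector of genomic context classes over
#'   the tag's hit loci (`"intergenic"`, `"repeat"`, `"genic"`).
#' @param band length band (default c(24, 32)).
#' @param require_unannotated if TRUE, repeat-derived loci disqualify the
#'   tag; default FALSE (repeat-derived intergenic piRNAs allowed).
#' @return list with `is_pirna` and `first_nt`.
#' @export
call_pirna <- function(tag_len, first_nt, locus_classes,
                       band = c(24L, 32L), require_unannotated = FALSE) {
  ok_classes <- if (require_unannotated) "intergenic" else
    c("intergenic", "repeat")
  ok <- tag_len >= band[1] && tag_len <= band[2] &&
    length(locus_classes) > 0 && all(locus_classes %in% ok_classes)
  list(is_pirna = ok, first_nt = first_nt)
}

# genomic context of hit loci against the feature table:
# "genic" if overlapping a gene model, "repeat" if overlapping a repeat,
# else "intergenic" (piRNA clusters are intergenic by construction)
locus_context <- function(hits, features) {
  if (nrow(hits) == 0L) return(character(0))
  genic <- features[features$class %in% c("gene", "exon", "intron",
                                          "utr3"), , drop = FALSE]
  reps <- features[features$class == "repeat", , drop = FALSE]
  vapply(seq_len(nrow(hits)), function(i) {
    s <- hits$start[i]; e <- hits$end[i]; r <- hits$ref[i]
    if (nrow(genic) > 0 && any(genic$contig == r & genic$start < e &
                                 genic$end > s)) return("genic")
    if (nrow(reps) > 0 && any(reps$contig == r & reps$start < e &
                                reps$end > s)) return("repeat")
    "intergenic"
  }, character(1))
}

#' Run the fixed-priority annotation cascade over a tag table
#'
#' Computes, for every tag, the set of categories it is eligible for and
#' assigns the first eligible category in priority order. Tags matching
#' nothing are `unannotated` (never an error).
#'
#' @param tags collapsed tag table (from [collapse_tags()]).
#' @param genome_hits perfect-match genome hit table from [map_tags()].
#' @param features feature annotation (as in a `toy_genome`).
#' @param ncrna_hits hit table of tags against the structural ncRNA
#'   reference set (<= 2 mismatches), with reference classes in
#'   `ncrna_class` (named vector: reference id -> class).
#' @param ncrna_class named character vector mapping ncRNA reference ids
#'   to their class (rRNA/tRNA/snRNA/snoRNA).
#' @param mature_refs,precursor_refs,mature_link conserved miRNA
#'   reference set (see [match_conserved_mirna()]).
#' @param novel_ids tag ids already identified as novel miRNA products
#'   (mature or star) by [discover_novel()]; empty for a pre-discovery
#'   pass.
#' @param priority category order (default [default_priority()]).
#' @param pirna_band,pirna_require_unannotated see [call_pirna()].
#' @param conserved_matches optional precomputed list (tag id ->
#'   [match_conserved_mirna()] result or NULL), to avoid recomputing the
#'   matching across cascade passes.
#' @return data.frame with one row per tag: `tag_id`, `category`,
#'   `evidence` (matched reference or locus summary), `mismatches`.
#' @export
annotate_cascade <- function(tags, genome_hits, features,
                             ncrna_hits = NULL, ncrna_class = character(0),
                             mature_refs = character(0),
                             precursor_refs = character(0),
                             mature_link = setNames(names(mature_refs),
                                                    names(mature_refs)),
                             novel_ids = character(0),
                             priority = default_priority(),
                             pirna_band = c(24L, 32L),
                             pirna_require_unannotated = FALSE,
                             conserved_matches = NULL) {
  n <- nrow(tags)
  eligible <- vector("list", n)
  evidence <- vector("list", n)
  names(eligible) <- tags$tag_id

  hit_by_tag <- if (nrow(genome_hits) > 0) {
    split(genome_hits, genome_hits$tag_id)
  } else list()
  nc_by_tag <- if (!is.null(ncrna_hits) && nrow(ncrna_hits) > 0) {
    split(ncrna_hits, ncrna_hits$tag_id)
  } else list()

  feat_classes <- c("repeat", "exon", "intron", "utr3")
  feats <- features[features$class %in% feat_classes, , drop = FALSE]

  for (i in seq_len(n)) {
    id <- tags$tag_id[i]
    elig <- character(0)
    ev <- list()

    nc <- nc_by_tag[[id]]
    if (!is.null(nc)) {
      cls <- ncrna_class[nc$ref]
      for (cl in unique(cls)) {
        elig <- c(elig, cl)
        best <- nc[cls == cl, , drop = FALSE]
        best <- best[which.min(best$mismatches), ]
        ev[[cl]] <- sprintf("%s mm=%d", best$ref, best$mismatches)
      }
    }

    cm <- if (!is.null(conserved_matches)) {
      conserved_matches[[id]]
    } else if (length(mature_refs) > 0) {
      match_conserved_mirna(tags$seq[i], mature_refs, precursor_refs,
                            mature_link)
    } else NULL
    if (!is.null(cm)) {
      elig <- c(elig, "miRNA_conserved")
      ev[["miRNA_conserved"]] <- sprintf("%s ov=%d mm=%d", cm$mature_id,
                                         cm$overlap, cm$mismatches)
    }

    gh <- hit_by_tag[[id]]
    if (!is.null(gh) && nrow(feats) > 0) {
      for (j in seq_len(nrow(gh))) {
        f <- feats[feats$contig == gh$ref[j] &
                     feats$start < gh$end[j] &
                     feats$end > gh$start[j], , drop = FALSE]
        if (nrow(f) == 0) next
        for (k in seq_len(nrow(f))) {
          cl <- f$class[k]
          if (cl == "repeat") cat_name <- "repeat"
          else if (cl %in% c("exon", "utr3")) {
            cat_name <- if (f$strand[k] == gh$strand[j]) "exon_sense" else
              "exon_antisense"
          } else {
            cat_name <- if (f$strand[k] == gh$strand[j]) "intron_sense" else
              "intron_antisense"
          }
          elig <- c(elig, cat_name)
          if (is.null(ev[[cat_name]])) {
            ev[[cat_name]] <- sprintf("%s@%s:%d", f$feature_id[k],
                                      gh$ref[j], gh$start[j])
          }
        }
      }
    }

    if (id %in% novel_ids) {
      elig <- c(elig, "miRNA_novel")
      ev[["miRNA_novel"]] <- "novel discovery"
    }

    if (!is.null(gh)) {
      ctx <- locus_context(gh, features)
      pc <- call_pirna(tags$length[i], substr(tags$seq[i], 1, 1), ctx,
                       band = pirna_band,
                       require_unannotated = pirna_require_unannotated)
      if (pc$is_pirna) {
        elig <- c(elig, "piRNA")
        ev[["piRNA"]] <- sprintf("5'%s loci=%d", pc$first_nt, nrow(gh))
      }
    }

    eligible[[i]] <- unique(elig)
    evidence[[i]] <- ev
  }

  category <- vapply(seq_len(n), function(i) {
    for (cl in priority) {
      if (cl == "unannotated") return("unannotated")
      if (cl %in% eligible[[i]]) return(cl)
    }
    "unannotated"
  }, character(1))
  evid <- vapply(seq_len(n), function(i) {
    e <- evidence[[i]][[category[i]]]
    if (is.null(e)) "" else e
  }, character(1))

  data.frame(tag_id = tags$tag_id, category = category, evidence = evid,
             stringsAsFactors = FALSE)
}

#' Per-stage piRNA sequence sets and pairwise overlaps
#'
#' Counts unique piRNA sequences per stage and the Venn-style overlaps
#' between stages.
#'
#' @param tags collapsed tag table.
#' @param records cascade output from [annotate_cascade()].
#' @param stages stage column names present in `tags`.
#' @return list with `per_stage` (named counts of unique piRNA sequences)
#'   and `overlap` (data.frame of pairwise intersection counts).
#' @export
pirna_stage_sets <- function(tags, records, stages = STAGES) {
  pir <- tags[records$category == "piRNA", , drop = FALSE]
  sets <- lapply(stages, function(s) pir$seq[pir[[s]] > 0])
  names(sets) <- stages
  per_stage <- vapply(sets, length, integer(1))
  combs <- utils::combn(stages, 2)
  overlap <- data.frame(
    stage_a = combs[1, ], stage_b = combs[2, ],
    shared = apply(combs, 2, function(p) {
      length(intersect(sets[[p[1]]], sets[[p[2]]]))
    }), stringsAsFactors = FALSE)
  list(per_stage = per_stage, overlap = overlap, sets = sets)
}
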