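# Synthetic multi-stage gonad small-RNA dataset generator.
#
# Builds a toy genome in which every feature the annotation cascade knows
# about is planted explicitly -- conserved and novel miRNA hairpins, decoy
# hairpins that each violate exactly one discovery criterion, intergenic
# piRNA clusters, structural ncRNAs, gene models with exons/introns/3'UTRs,
# and repeats -- then simulates three stage-specific libraries (ovary,
# ovotestis, testis) of adapter-carrying raw reads with a complete truth
# table. Planted hairpins are verified against the discovery criteria
# checker during generation, so the planted/decoy contract is enforced by
# construction.

STAGES <- c("ovary", "ovotestis", "testis")
DEFAULT_ADAPTER3 <- "TCGTATGCCGTCTTCTGCTTG"
FEATURE_SPACING <- 200L

#' Specification of a synthetic toy genome
#'
#' @param n_novel_hairpins number of planted novel miRNA hairpins, each
#'   constructed to satisfy every discovery criterion.
#' @param n_conserved_hairpins number of planted hairpins whose mature
#'   sequences are also emitted as a miRBase-style reference set.
#' @param n_pirna_clusters number of intergenic piRNA clusters.
#' @param n_decoy_ncrnas named integer vector: planted structural ncRNAs
#'   per class (rRNA, tRNA, snRNA, snoRNA).
#' @param n_gene_models number of gene models (3 exons, 2 introns, a 3'UTR).
#' @param n_repeats number of repeat elements (each planted at two loci).
#' @param decoy_reasons character vector naming, for each decoy hairpin,
#'   the single discovery criterion it violates. Allowed reasons:
#'   free_energy, min_pairs, max_loop, max_bulge, max_asymmetry,
#'   mature_length, cut_depth, max_copies.
#' @param genome_length total genome length; `NULL` (default) sizes the
#'   genome to fit all features with 200 nt spacing. An explicit length too
#'   small to hold the features is a capacity error.
#' @param rng_seed integer seed; identical specs and seeds give
#'   byte-identical genomes.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(n_novel_hairpins = 20L,
                        n_conserved_hairpins = 8L,
                        n_pirna_clusters = 3L,
                        n_decoy_ncrnas = c(rRNA = 2L, tRNA = 2L,
                                           snRNA = 2L, snoRNA = 2L),
                        n_gene_models = 3L,
                        n_repeats = 2L,
                        decoy_reasons = c("free_energy", "min_pairs",
                                          "max_loop", "max_bulge",
                                          "max_asymmetry", "mature_length",
                                          "mature_length", "cut_depth",
                                          "cut_depth", "max_copies"),
                        genome_length = NULL,
                        rng_seed = 1L) {
  counts <- c(n_novel_hairpins, n_conserved_hairpins, n_pirna_clusters,
              n_decoy_ncrnas, n_gene_models, n_repeats)
  if (any(counts < 0)) stop("all feature counts must be >= 0")
  ok <- c("free_energy", "min_pairs", "max_loop", "max_bulge",
          "max_asymmetry", "mature_length", "cut_depth", "max_copies")
  if (length(decoy_reasons) > 0 && !all(decoy_reasons %in% ok)) {
    stop("unknown decoy reason(s): ",
         paste(setdiff(decoy_reasons, ok), collapse = ", "))
  }
  structure(list(
    n_novel_hairpins = as.integer(n_novel_hairpins),
    n_conserved_hairpins = as.integer(n_conserved_hairpins),
    n_pirna_clusters = as.integer(n_pirna_clusters),
    n_decoy_ncrnas = n_decoy_ncrnas,
    n_gene_models = as.integer(n_gene_models),
    n_repeats = as.integer(n_repeats),
    decoy_reasons = decoy_reasons,
    genome_length = genome_length,
    rng_seed = as.integer(rng_seed)
  ), class = "genome_spec")
}

# ---- hairpin constructors -------------------------------------------------

# A candidate record in the shape evaluate_precursor_criteria() expects,
# built directly from a planted construct (depth/copies supplied).
planted_candidate <- function(precursor, m_start, m_end, depth, copies) {
  fr <- fold(precursor)
  star <- infer_star_arm(fr, m_start, m_end)
  dup <- evaluate_duplex(fr, c(m_start, m_end), star)
  list(mature_length = m_end - m_start, depth = depth, copies = copies,
       delta_g = fr$delta_g, duplex = dup, fold = fr)
}

# perfect stem-loop: mature + loop + reverse complement of mature
make_perfect_hairpin <- function(mature_len = 22L, loop_len = 12L) {
  repeat {
    mature <- random_dna(1, mature_len)
    loop <- random_dna(1, loop_len)
    precursor <- paste0(mature, loop, revcomp(mature))
    cand <- planted_candidate(precursor, 0L, mature_len, 30L, 1L)
    ev <- evaluate_precursor_criteria(cand, discovery_params())
    if (ev$accept) {
      return(list(precursor = precursor, mature = mature,
                  m_start = 0L, m_end = mature_len,
                  s_start = mature_len + loop_len,
                  s_end = nchar(precursor)))
    }
  }
}

# Decoy constructors. Each builds a hairpin violating exactly one
# criterion under the default parameters; non-stem positions use bases
# that cannot pair with the stem so the minimum-energy structure is the
# designed one. Verified against the checker before planting.
make_decoy_hairpin <- function(reason) {
  build <- switch(reason,
    free_energy = function() {
      # AT-only 15-bp stem: enough pairs, too little stacking energy
      core <- paste(rep(c("A", "T"), length.out = 15), collapse = "")
      mature <- paste0("CCC", core, "CCCC")
      list(mature = mature, loop = strrep("C", 12), star = revcomp(core))
    },
    min_pairs = function() {
      # 13 GC pairs only (< 14); A elsewhere is inert (no T in stem)
      core <- paste(rep(c("G", "C"), length.out = 13), collapse = "")
      mature <- paste0("AAAA", core, "AAAAA")
      list(mature = mature, loop = strrep("A", 12), star = revcomp(core))
    },
    max_loop = function() {
      core <- paste(rep(c("G", "C"), length.out = 16), collapse = "")
      mature <- paste0("AAA", core, "AAA")
      list(mature = mature, loop = strrep("A", 40), star = revcomp(core))
    },
    max_bulge = function() {
      core <- paste(rep(c("G", "C"), length.out = 16), collapse = "")
      mature <- paste0("AAA", core, "AAA")
      rc <- revcomp(core)
      star <- paste0(substr(rc, 1, 8), strrep("A", 5), substr(rc, 9, 16))
      list(mature = mature, loop = strrep("A", 12), star = star)
    },
    max_asymmetry = function() {
      core <- paste(rep(c("G", "C"), length.out = 16), collapse = "")
      mature <- paste0("AAA", core, "AAA")
      rc <- revcomp(core)
      star <- paste0(substr(rc, 1, 6), strrep("A", 4), substr(rc, 7, 11),
                     strrep("A", 2), substr(rc, 12, 16))
      list(mature = mature, loop = strrep("A", 12), star = star)
    },
    mature_length = function() {
      mature <- random_dna(1, 27)
      list(mature = mature, loop = random_dna(1, 12), star = revcomp(mature))
    },
    cut_depth = function() {       # structurally perfect; starved of reads
      mature <- random_dna(1, 22)
      list(mature = mature, loop = random_dna(1, 12), star = revcomp(mature))
    },
    max_copies = function() {      # structurally perfect; planted 11 times
      mature <- random_dna(1, 22)
      list(mature = mature, loop = random_dna(1, 12), star = revcomp(mature))
    },
    stop("unknown decoy reason: ", reason)
  )
  # depth/copies as the default profiles will realise them
  depth <- if (reason == "cut_depth") 2L else 30L
  copies <- if (reason == "max_copies") 22L else 1L
  repeat {
    p <- build()
    precursor <- paste0(p$mature, p$loop, p$star)
    cand <- planted_candidate(precursor, 0L, nchar(p$mature), depth, copies)
    ev <- evaluate_precursor_criteria(cand, discovery_params())
    if (!ev$accept && identical(sort(ev$reasons), reason)) {
      return(list(precursor = precursor, mature = p$mature,
                  m_start = 0L, m_end = nchar(p$mature),
                  s_start = nchar(p$mature) + nchar(p$loop),
                  s_end = nchar(precursor)))
    }
  }
}

conserved_names <- function(n) {
  canon <- c("syn-mir-17a", "syn-mir-18a", "syn-mir-19a", "syn-mir-19b-1",
             "syn-mir-19b-2", "syn-mir-20a", "syn-mir-92a", "syn-mir-92b")
  if (n <= length(canon)) canon[seq_len(n)]
  else c(canon, sprintf("syn-mir-%d", 100 + seq_len(n - length(canon))))
}

# ---- genome assembly ------------------------------------------------------

#' Build a toy genome with planted small-RNA features
#'
#' Assembles the genome, the feature annotation, and the reference sets
#' (structural ncRNAs, conserved mature miRNAs and their precursors) that
#' the downstream annotation stages consume. Every planted novel hairpin is
#' checked against [evaluate_precursor_criteria()] during generation;
#' every decoy hairpin is checked to fail for exactly its designated
#' criterion.
#'
#' @param spec a [genome_spec()].
#' @return object of class `toy_genome`: list with `genome` (named
#'   character, one contig), `features` (data.frame: feature_id, class,
#'   contig, start, end, strand, decoy_reason, group -- coordinates 0-based
#'   half-open), `hairpins` (per-hairpin precursor/mature/star details),
#'   `references` (ncRNA set with classes, conserved mature and precursor
#'   sets, mature-to-precursor links), and the originating [genome_spec()].
#' @export
build_toy_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$rng_seed, build_toy_genome_impl(spec))
}

build_toy_genome_impl <- function(spec) {
  blocks <- list()   # each: list(seq, rows = data.frame of feature rows)
  hairpins <- list()
  ncrna_refs <- character(0); ncrna_class <- character(0)
  mature_refs <- character(0); precursor_refs <- character(0)

  # pad_char: inert base wrapped around decoy precursors so that the
  # in-genome structural context cannot change their designed metrics
  add_hairpin_block <- function(name, class, hp, reason = NA_character_,
                                group = name, pad_char = NULL) {
    seq <- hp$precursor
    off <- 0L
    if (!is.null(pad_char)) {
      pad <- strrep(pad_char, 15L)
      seq <- paste0(pad, hp$precursor, pad)
      off <- 15L
    }
    rows <- data.frame(feature_id = name, class = class,
                       length = nchar(hp$precursor), strand = "+",
                       decoy_reason = reason, group = group,
                       offset = off, stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1L]] <<- list(seq = seq, rows = rows)
    hairpins[[name]] <<- c(hp, list(feature_id = name, class = class,
                                    decoy_reason = reason))
  }

  # conserved hairpins (mature sequences double as the reference set)
  cnames <- conserved_names(spec$n_conserved_hairpins)
  for (i in seq_len(spec$n_conserved_hairpins)) {
    hp <- make_perfect_hairpin()
    add_hairpin_block(cnames[i], "conserved_hairpin", hp)
    # both duplex strands are part of the mature reference set, as in
    # miRBase-style references carrying -5p and -3p entries
    mature_refs[cnames[i]] <- hp$mature
    mature_refs[paste0(cnames[i], "-star")] <-
      substr(hp$precursor, hp$s_start + 1L, hp$s_end)
    precursor_refs[cnames[i]] <- hp$precursor
  }

  for (i in seq_len(spec$n_novel_hairpins)) {
    hp <- make_perfect_hairpin()
    add_hairpin_block(sprintf("novel_hp_%02d", i), "novel_hairpin", hp)
  }

  decoy_pads <- c(free_energy = "C", min_pairs = "A", max_loop = "A",
                  max_bulge = "A", max_asymmetry = "A")
  for (i in seq_along(spec$decoy_reasons)) {
    reason <- spec$decoy_reasons[i]
    hp <- make_decoy_hairpin(reason)
    id <- sprintf("decoy_hp_%02d", i)
    pad <- if (reason %in% names(decoy_pads)) decoy_pads[[reason]] else NULL
    if (reason == "max_copies") {
      for (k in 1:11) {
        add_hairpin_block(sprintf("%s_copy%02d", id, k), "decoy_hairpin",
                          hp, reason, group = id, pad_char = pad)
      }
    } else {
      add_hairpin_block(id, "decoy_hairpin", hp, reason, pad_char = pad)
    }
  }

  nc_lens <- c(rRNA = 120L, tRNA = 72L, snRNA = 100L, snoRNA = 80L)
  for (cls in names(spec$n_decoy_ncrnas)) {
    for (i in seq_len(spec$n_decoy_ncrnas[[cls]])) {
      id <- sprintf("%s_%d", cls, i)
      s <- random_dna(1, nc_lens[[cls]])
      blocks[[length(blocks) + 1L]] <- list(
        seq = s,
        rows = data.frame(feature_id = id, class = cls, length = nchar(s),
                          strand = "+", decoy_reason = NA_character_,
                          group = id, stringsAsFactors = FALSE))
      ncrna_refs[id] <- s
      ncrna_class[id] <- cls
    }
  }

  for (g in seq_len(spec$n_gene_models)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- sprintf("gene_%d", g)
    parts <- list(
      c("exon", 300L, sprintf("%s_exon1", gid)),
      c("intron", 500L, sprintf("%s_intron1", gid)),
      c("exon", 300L, sprintf("%s_exon2", gid)),
      c("intron", 500L, sprintf("%s_intron2", gid)),
      c("exon", 500L, sprintf("%s_exon3", gid))
    )
    seqs <- vapply(parts, function(p) random_dna(1, as.integer(p[2])),
                   character(1))
    gene_seq <- paste(seqs, collapse = "")
    offs <- cumsum(c(0L, vapply(parts, function(p) as.integer(p[2]),
                                integer(1))))
    rows <- do.call(rbind, lapply(seq_along(parts), function(k) {
      data.frame(feature_id = parts[[k]][3], class = parts[[k]][1],
                 length = as.integer(parts[[k]][2]), strand = strand,
                 decoy_reason = NA_character_, group = gid,
                 offset = offs[k], stringsAsFactors = FALSE)
    }))
    # 3'UTR: last 300 nt of the terminal exon (strand-aware)
    utr_off <- if (strand == "+") offs[6L] - 300L else offs[5L]
    rows <- rbind(rows,
      data.frame(feature_id = sprintf("%s_utr3", gid), class = "utr3",
                 length = 300L, strand = strand,
                 decoy_reason = NA_character_, group = gid,
                 offset = utr_off, stringsAsFactors = FALSE))
    gene_row <- data.frame(feature_id = gid, class = "gene",
                           length = nchar(gene_seq), strand = strand,
                           decoy_reason = NA_character_, group = gid,
                           offset = 0L, stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1L]] <- list(seq = gene_seq,
                                          rows = rbind(gene_row, rows))
  }

  for (r in seq_len(spec$n_repeats)) {
    unit <- random_dna(1, 400L)
    for (k in 1:2) {
      blocks[[length(blocks) + 1L]] <- list(
        seq = unit,
        rows = data.frame(feature_id = sprintf("repeat_%d_copy%d", r, k),
                          class = "repeat", length = 400L, strand = "+",
                          decoy_reason = NA_character_,
                          group = sprintf("repeat_%d", r),
                          stringsAsFactors = FALSE))
    }
  }

  for (p in seq_len(spec$n_pirna_clusters)) {
    s <- random_dna(1, 2000L)
    blocks[[length(blocks) + 1L]] <- list(
      seq = s,
      rows = data.frame(feature_id = sprintf("pirna_cluster_%d", p),
                        class = "pirna_cluster", length = 2000L,
                        strand = "+", decoy_reason = NA_character_,
                        group = sprintf("pirna_cluster_%d", p),
                        stringsAsFactors = FALSE))
  }

  # lay blocks onto the contig with fixed spacing
  feature_len <- sum(vapply(blocks, function(b) nchar(b$seq), numeric(1)))
  needed <- feature_len + FEATURE_SPACING * (length(blocks) + 1L)
  glen <- if (is.null(spec$genome_length)) as.integer(needed) else
    as.integer(spec$genome_length)
  if (glen < needed) {
    stop("capacity error: features need ", needed,
         " nt but genome_length is ", glen)
  }

  pieces <- character(0)
  rows_all <- list()
  pos <- 0L
  for (b in blocks) {
    pieces <- c(pieces, random_dna(1, FEATURE_SPACING))
    pos <- pos + FEATURE_SPACING
    rows <- b$rows
    off <- if ("offset" %in% names(rows)) rows$offset else
      rep(0L, nrow(rows))
    rows$start <- pos + off
    rows$end <- rows$start + rows$length
    rows$offset <- NULL
    rows_all[[length(rows_all) + 1L]] <- rows
    pieces <- c(pieces, b$seq)
    pos <- pos + nchar(b$seq)
  }
  if (glen > pos) pieces <- c(pieces, random_dna(1, glen - pos))
  genome <- paste(pieces, collapse = "")

  features <- if (length(rows_all) > 0) do.call(rbind, rows_all) else
    data.frame(feature_id = character(0), class = character(0),
               length = integer(0), strand = character(0),
               decoy_reason = character(0), group = character(0),
               start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  if (nrow(features) > 0) {
    features$contig <- "contig1"
    features <- features[, c("feature_id", "class", "contig", "start",
                             "end", "strand", "decoy_reason", "group")]
  } else {
    features$contig <- character(0)
  }
  rownames(features) <- NULL

  # absolute coordinates for hairpin arms
  for (id in names(hairpins)) {
    row <- features[features$feature_id == id, ]
    hairpins[[id]]$start <- row$start
    hairpins[[id]]$end <- row$end
  }

  structure(list(
    genome = c(contig1 = genome),
    features = features,
    hairpins = hairpins,
    references = list(ncrna = ncrna_refs, ncrna_class = ncrna_class,
                      mature = mature_refs, precursor = precursor_refs,
                      mature_link = setNames(
                        sub("-star$", "", names(mature_refs)),
                        names(mature_refs))),
    spec = spec
  ), class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy genome:", nchar(x$genome[[1]]), "nt,", nrow(x$features),
      "features\n")
  print(table(x$features$class))
  invisible(x)
}

#' Write a toy genome to disk (FASTA + GFF3 + reference sets)
#'
#' @param toy a `toy_genome`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_toy_genome <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(toy$genome, file.path(dir, "genome.fa"))
  write_gff3(toy$features, file.path(dir, "features.gff3"))
  if (length(toy$references$ncrna)) {
    write_fasta(toy$references$ncrna, file.path(dir, "ncrna.fa"))
  }
  if (length(toy$references$mature)) {
    write_fasta(toy$references$mature, file.path(dir, "mature.fa"))
    write_fasta(toy$references$precursor, file.path(dir, "precursor.fa"))
  }
  invisible(dir)
}

# ---- library simulation ---------------------------------------------------

#' Per-stage library profile for the read simulator
#'
#' @param stage one of `"ovary"`, `"ovotestis"`, `"testis"`.
#' @param abundance named numeric vector: requested read count per read
#'   source (feature id, or `<id>_star` / `<id>_as` derivatives).
#' @param isomir isomiR jitter for conserved-miRNA reads: list with `p5`
#'   (named probabilities over 5' offsets), `p3` (3' offsets), `nta_prob`
#'   (chance of one non-templated 3' addition) and `nta_bases`.
#' @param pirna_first_u_prob probability that a piRNA read starts on a
#'   genomic U; enforced by start-site choice so reads stay exactly
#'   genome-matched.
#' @param pirna_len_weights named weights over piRNA read lengths.
#' @param adapter3 3' adapter sequence appended to every insert.
#' @param noise_read_fraction fraction of the library made of uniform
#'   random (unannotatable) reads.
#' @return object of class `library_profile`.
#' @export
library_profile <- function(stage, abundance,
                            isomir = list(
                              p5 = c(`-1` = 0.15, `0` = 0.70, `1` = 0.15),
                              p3 = c(`-2` = 0.10, `-1` = 0.15, `0` = 0.50,
                                     `1` = 0.15, `2` = 0.10),
                              nta_prob = 0.05,
                              nta_bases = c("A", "T")),
                            pirna_first_u_prob = 0.8,
                            pirna_len_weights = c(`24` = 0.08, `25` = 0.12,
                                                  `26` = 0.20, `27` = 0.22,
                                                  `28` = 0.20, `29` = 0.10,
                                                  `30` = 0.08),
                            adapter3 = DEFAULT_ADAPTER3,
                            noise_read_fraction = 0.02) {
  stopifnot(stage %in% STAGES,
            all(abundance >= 0),
            pirna_first_u_prob >= 0, pirna_first_u_prob <= 1,
            noise_read_fraction >= 0, noise_read_fraction < 1,
            nchar(adapter3) > 0)
  structure(list(stage = stage, abundance = abundance, isomir = isomir,
                 pirna_first_u_prob = pirna_first_u_prob,
                 pirna_len_weights = pirna_len_weights,
                 adapter3 = adapter3,
                 noise_read_fraction = noise_read_fraction),
            class = "library_profile")
}

#' Default three-stage profiles for a toy genome
#'
#' Encodes the stage structure the analysis assumes: conserved miRNAs
#' expressed in all three gonad stages (with isomiR jitter and star-strand
#' reads for alternate precursors), novel miRNAs mostly stage-specific,
#' piRNA clusters testis-enriched with a 0.8 5'-U probability, structural
#' ncRNA / exonic / intronic / repeat degradation fragments, and 2% random
#' noise reads. The cut-depth decoy receives exactly 2 reads in total.
#'
#' @param toy a `toy_genome`.
#' @return list of three `library_profile` objects (ovary, ovotestis,
#'   testis).
#' @export
default_profiles <- function(toy) {
  f <- toy$features
  ab <- list(ovary = numeric(0), ovotestis = numeric(0),
             testis = numeric(0))
  add <- function(src, v) {
    for (s in STAGES) ab[[s]][src] <<- v[[s]]
  }

  cons <- f$feature_id[f$class == "conserved_hairpin"]
  for (i in seq_along(cons)) {
    add(cons[i], list(ovary = 40 + 2 * i, ovotestis = 60 + 3 * i,
                      testis = 50 + 2 * i))
    if (i %% 2L == 0L) {
      add(paste0(cons[i], "_star"),
          list(ovary = 12, ovotestis = 15, testis = 13))
    }
  }

  nov <- f$feature_id[f$class == "novel_hairpin"]
  for (i in seq_along(nov)) {
    v <- list(ovary = 0, ovotestis = 0, testis = 0)
    if (i %% 4L == 1L) {
      v <- list(ovary = 30 + i, ovotestis = 24 + i, testis = 27 + i)
    } else {
      v[[STAGES[(i %% 3L) + 1L]]] <- 30 + i
    }
    add(nov[i], v)
    if (i %% 3L == 0L) {
      sv <- lapply(v, function(x) if (x > 0) 8 else 0)
      add(paste0(nov[i], "_star"), sv)
    }
  }

  dec <- f[f$class == "decoy_hairpin", ]
  for (grp in unique(dec$group)) {
    src <- dec$feature_id[dec$group == grp][1L]   # one source per decoy
    if (dec$decoy_reason[dec$group == grp][1L] == "cut_depth") {
      add(src, list(ovary = 2, ovotestis = 0, testis = 0))
    } else {
      add(src, list(ovary = 30, ovotestis = 30, testis = 30))
    }
  }

  pir <- f$feature_id[f$class == "pirna_cluster"]
  for (i in seq_along(pir)) {
    add(pir[i], list(ovary = 600 + 50 * i, ovotestis = 800 + 50 * i,
                     testis = 1200 + 50 * i))
  }

  for (id in f$feature_id[f$class %in% c("rRNA", "tRNA", "snRNA",
                                         "snoRNA")]) {
    add(id, list(ovary = 40, ovotestis = 40, testis = 40))
  }
  for (id in f$feature_id[f$class == "exon"]) {
    add(id, list(ovary = 30, ovotestis = 30, testis = 30))
    add(paste0(id, "_as"), list(ovary = 8, ovotestis = 8, testis = 8))
  }
  for (id in f$feature_id[f$class == "intron"]) {
    add(id, list(ovary = 25, ovotestis = 25, testis = 25))
    add(paste0(id, "_as"), list(ovary = 6, ovotestis = 6, testis = 6))
  }
  rep_feats <- f[f$class == "repeat", ]
  for (grp in unique(rep_feats$group)) {
    src <- rep_feats$feature_id[rep_feats$group == grp][1L]
    add(src, list(ovary = 30, ovotestis = 30, testis = 30))
  }

  lapply(STAGES, function(s) library_profile(s, ab[[s]]))
}

#' Simulate three-stage small-RNA libraries from a toy genome
#'
#' Every read is a feature subsequence (with isomiR jitter for conserved
#' miRNA sources and 5'-U start-site enforcement for piRNA sources) plus
#' the 3' adapter, padded with A to the 50 nt raw-read layout. A truth
#' table maps every read to its source feature, stage and jitter offsets.
#'
#' @param toy a `toy_genome`.
#' @param profiles list of three [library_profile()]s covering the stages.
#' @param seed RNG seed (defaults to the genome spec seed + 1000).
#' @param out_dir if non-NULL, FASTQ files and the truth TSV are written
#'   here.
#' @return list with `libraries` (per stage: data.frame id/seq/qual) and
#'   `truth` (data.frame read_id, stage, source, feature_id, class,
#'   insert, length, off5, off3, nta).
#' @export
simulate_libraries <- function(toy, profiles = default_profiles(toy),
                               seed = toy$spec$rng_seed + 1000L,
                               out_dir = NULL) {
  stopifnot(inherits(toy, "toy_genome"))
  stages <- vapply(profiles, function(p) p$stage, character(1))
  if (!setequal(stages, STAGES)) {
    stop("profiles must cover ovary, ovotestis and testis")
  }
  res <- with_seed(seed, simulate_libraries_impl(toy, profiles))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(res$libraries)) {
      lib <- res$libraries[[s]]
      x <- Biostrings::DNAStringSet(lib$seq)
      names(x) <- lib$id
      Biostrings::writeXStringSet(
        x, file.path(out_dir, paste0(s, ".fastq")), format = "fastq",
        qualities = Biostrings::BStringSet(lib$qual))
    }
    write_tsv(res$truth, file.path(out_dir, "truth.tsv"))
  }
  res
}

simulate_libraries_impl <- function(toy, profiles) {
  genome <- toy$genome[[1]]
  f <- toy$features
  feat_by_id <- split(f, f$feature_id)
  libraries <- list()
  truth <- list()

  source_insert <- function(src, prof) {
    # returns list(insert, feature_id, class, off5, off3, nta)
    base_id <- sub("_(star|as)$", "", src)
    suffix <- if (grepl("_star$", src)) "star" else
      if (grepl("_as$", src)) "as" else ""
    if (!base_id %in% names(feat_by_id)) {
      stop("abundance requested for unknown feature: ", src)
    }
    row <- feat_by_id[[base_id]][1L, ]
    cls <- row$class
    if (cls %in% c("conserved_hairpin", "novel_hairpin", "decoy_hairpin")) {
      hp <- toy$hairpins[[base_id]]
      if (suffix == "star") {
        ins <- substr(hp$precursor, hp$s_start + 1L, hp$s_end)
        return(list(insert = ins, feature_id = base_id, class = cls,
                    off5 = 0L, off3 = 0L, nta = ""))
      }
      if (cls == "conserved_hairpin") {
        d5 <- as.integer(sample(names(prof$isomir$p5), 1,
                                prob = prof$isomir$p5))
        d3 <- as.integer(sample(names(prof$isomir$p3), 1,
                                prob = prof$isomir$p3))
        a <- hp$m_start + d5
        b <- hp$m_end + d3
        if (a < 0L) { a <- 0L; d5 <- -hp$m_start }
        ins <- substr(hp$precursor, a + 1L, b)
        nta <- ""
        if (runif(1) < prof$isomir$nta_prob) {
          nb <- sample(prof$isomir$nta_bases, 1)
          nxt <- substr(hp$precursor, b + 1L, b + 1L)
          if (identical(nb, nxt) && nzchar(nxt)) {
            d3 <- d3 + 1L                      # actually templated
            ins <- substr(hp$precursor, a + 1L, b + 1L)
          } else {
            # pick an addition that stays non-templated in either
            # orientation, so the read cannot silently become a genomic
            # (antisense) match; skip the addition if no base qualifies
            ok <- vapply(prof$isomir$nta_bases, function(x) {
              !identical(x, nxt) &&
                !grepl(revcomp(paste0(ins, x)), hp$precursor, fixed = TRUE)
            }, logical(1))
            if (!ok[[nb]]) nb <- c(names(ok)[ok], "")[1L]
            if (nzchar(nb)) {
              ins <- paste0(ins, nb)
              nta <- nb
            }
          }
        }
        return(list(insert = ins, feature_id = base_id, class = cls,
                    off5 = d5, off3 = d3, nta = nta))
      }
      ins <- substr(hp$precursor, hp$m_start + 1L, hp$m_end)
      return(list(insert = ins, feature_id = base_id, class = cls,
                  off5 = 0L, off3 = 0L, nta = ""))
    }
    if (cls == "pirna_cluster") {
      len <- as.integer(sample(names(prof$pirna_len_weights), 1,
                               prob = prof$pirna_len_weights))
      reg <- substr(genome, row$start + 1L, row$end)
      starts_t <- which(strsplit(reg, "")[[1]] == "T")
      starts_t <- starts_t[starts_t + len - 1L <= nchar(reg)]
      all_starts <- seq_len(nchar(reg) - len + 1L)
      starts_nt <- setdiff(all_starts, starts_t)
      use_t <- runif(1) < prof$pirna_first_u_prob
      pool <- if (use_t) starts_t else starts_nt
      if (length(pool) == 0L) pool <- all_starts
      st <- if (length(pool) == 1L) pool else sample(pool, 1)
      ins <- substr(reg, st, st + len - 1L)
      return(list(insert = ins, feature_id = base_id, class = cls,
                  off5 = 0L, off3 = 0L, nta = ""))
    }
    # degradation fragment from a structural ncRNA / exon / intron / repeat
    len <- sample(18:30, 1)
    reg <- substr(genome, row$start + 1L, row$end)
    st <- sample(seq_len(nchar(reg) - len + 1L), 1)
    ins <- substr(reg, st, st + len - 1L)
    sense_strand <- row$strand
    antisense <- identical(suffix, "as")
    if ((sense_strand == "-") != antisense) ins <- revcomp(ins)
    cls_out <- if (cls %in% c("exon", "intron")) {
      paste0(cls, if (antisense) "_antisense" else "_sense")
    } else cls
    list(insert = ins, feature_id = base_id, class = cls_out,
         off5 = 0L, off3 = 0L, nta = "")
  }

  for (prof in profiles) {
    stage <- prof$stage
    srcs <- sort(names(prof$abundance))
    src_v <- character(0); feat_v <- character(0); cls_v <- character(0)
    ins_v <- character(0); off5_v <- integer(0); off3_v <- integer(0)
    nta_v <- character(0)
    for (src in srcs) {
      n <- as.integer(round(prof$abundance[[src]]))
      if (n <= 0L) next
      its <- lapply(seq_len(n), function(k) source_insert(src, prof))
      src_v <- c(src_v, rep(src, n))
      feat_v <- c(feat_v, vapply(its, `[[`, "", "feature_id"))
      cls_v <- c(cls_v, vapply(its, `[[`, "", "class"))
      ins_v <- c(ins_v, vapply(its, `[[`, "", "insert"))
      off5_v <- c(off5_v, vapply(its, function(x) as.integer(x$off5), 1L))
      off3_v <- c(off3_v, vapply(its, function(x) as.integer(x$off3), 1L))
      nta_v <- c(nta_v, vapply(its, `[[`, "", "nta"))
    }
    n_feat <- length(ins_v)
    n_noise <- as.integer(round(prof$noise_read_fraction * n_feat /
                                  (1 - prof$noise_read_fraction)))
    if (n_noise > 0L) {
      noise_ins <- vapply(seq_len(n_noise),
                          function(k) random_dna(1, sample(18:30, 1)),
                          character(1))
      src_v <- c(src_v, rep("noise", n_noise))
      feat_v <- c(feat_v, rep("noise", n_noise))
      cls_v <- c(cls_v, rep("noise", n_noise))
      ins_v <- c(ins_v, noise_ins)
      off5_v <- c(off5_v, rep(0L, n_noise))
      off3_v <- c(off3_v, rep(0L, n_noise))
      nta_v <- c(nta_v, rep("", n_noise))
    }
    tr <- data.frame(
      read_id = sprintf("%s_r%06d", stage, seq_along(ins_v)),
      stage = stage, source = src_v, feature_id = feat_v, class = cls_v,
      insert = ins_v, length = nchar(ins_v), off5 = off5_v,
      off3 = off3_v, nta = nta_v, stringsAsFactors = FALSE)
    raw <- substr(paste0(tr$insert, prof$adapter3, strrep("A", 50)), 1, 50)
    libraries[[stage]] <- data.frame(id = tr$read_id, seq = raw,
                                     qual = strrep("I", 50),
                                     stringsAsFactors = FALSE)
    truth[[stage]] <- tr
  }
  list(libraries = libraries[STAGES],
       truth = do.call(rbind, truth[STAGES]))
}
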