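# End-to-end pipeline: simulate -> preprocess -> map -> annotate ->
# discover -> quantify -> evolve -> scan, from one structured config.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with the synthetic-data spec and the
#' seeds, so a run is fully reproducible from the config alone. The config
#' round-trips through YAML serialization unchanged.
#'
#' @param spec a [genome_spec()] describing the synthetic dataset.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir output directory (NULL = keep results in memory only).
#' @param discovery a [discovery_params()].
#' @param priority annotation category order.
#' @param pirna_band piRNA length band.
#' @param pirna_require_unannotated see [call_pirna()].
#' @param specificity_threshold RPM presence threshold.
#' @param cluster_max_gap cluster chaining gap, bp.
#' @param consensus_case_threshold consensus uppercase threshold.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param min_len,max_len insert length bounds for preprocessing.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = genome_spec(), seed = 1L,
                            out_dir = NULL,
                            discovery = discovery_params(),
                            priority = default_priority(),
                            pirna_band = c(24L, 32L),
                            pirna_require_unannotated = FALSE,
                            specificity_threshold = 1,
                            cluster_max_gap = 10000L,
                            consensus_case_threshold = 0.9,
                            bootstrap_replicates = 100L,
                            min_len = 18L, max_len = 32L) {
  structure(list(spec = spec, seed = as.integer(seed), out_dir = out_dir,
                 discovery = discovery, priority = priority,
                 pirna_band = as.integer(pirna_band),
                 pirna_require_unannotated = pirna_require_unannotated,
                 specificity_threshold = specificity_threshold,
                 cluster_max_gap = as.integer(cluster_max_gap),
                 consensus_case_threshold = consensus_case_threshold,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline config (YAML)
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` returns the path; `read_config` the restored
#'   config.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- unclass(x$spec)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::yaml.load_file(path)
  x$spec$n_decoy_ncrnas <- unlist(x$spec$n_decoy_ncrnas)
  if (is.null(x$spec$decoy_reasons)) {
    x$spec$decoy_reasons <- character(0)
  }
  spec <- do.call(genome_spec, x$spec)
  x$spec <- NULL
  x$discovery <- do.call(discovery_params, x$discovery)
  do.call(pipeline_config, c(list(spec = spec), x))
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes all stages in order on the synthetic dataset described by the
#' config and collects per-stage results plus a run manifest (seeds,
#' parameters, per-stage tallies and conservation checks). Re-running
#' with the same config reproduces all outputs.
#'
#' @param config a [pipeline_config()].
#' @param profiles optional list of three [library_profile()]s overriding
#'   [default_profiles()] (e.g. scaled-down or stress-test libraries).
#' @param quiet suppress progress messages (written to stderr).
#' @return object of class `srnaflow_result`; see the elements `toy`,
#'   `sim`, `tags`, `annotation`, `novel`, `expression`, `de`, `isomir`,
#'   `bias`, `arm_usage`, `clusters`, `copy_number`, `phylo`, `sites`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), profiles = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[srnaflow] ", ...)
  t0 <- Sys.time()

  say("simulate: building toy genome and libraries")
  toy <- build_toy_genome(config$spec)
  if (is.null(profiles)) profiles <- default_profiles(toy)
  sim <- simulate_libraries(toy, profiles,
                            seed = config$spec$rng_seed + 1000L)

  say("preprocess: trimming and collapsing")
  adapter3 <- profiles[[1]]$adapter3
  cleaned <- lapply(sim$libraries, function(lib) {
    filter_and_trim(lib, adapter3 = adapter3, min_len = config$min_len,
                    max_len = config$max_len)
  })
  tags <- collapse_tags(lapply(cleaned, function(x) x$clean$insert))
  clean_totals <- vapply(cleaned, function(x) nrow(x$clean), integer(1))

  say("map: ", nrow(tags), " unique tags against the genome")
  gindex <- build_index(toy$genome)
  genome_hits <- map_tags(setNames(tags$seq, tags$tag_id), gindex,
                          max_mismatches = 0L)
  ncrna_hits <- NULL
  if (length(toy$references$ncrna) > 0) {
    nindex <- build_index(toy$references$ncrna)
    ncrna_hits <- map_tags(setNames(tags$seq, tags$tag_id), nindex,
                           max_mismatches = 2L)
  }

  say("annotate: pre-discovery cascade")
  cons_matches <- lapply(setNames(tags$seq, tags$tag_id), function(s) {
    if (length(toy$references$mature) == 0) return(NULL)
    match_conserved_mirna(s, toy$references$mature,
                          toy$references$precursor,
                          toy$references$mature_link)
  })
  cascade_args <- list(
    tags = tags, genome_hits = genome_hits, features = toy$features,
    ncrna_hits = ncrna_hits, ncrna_class = toy$references$ncrna_class,
    mature_refs = toy$references$mature,
    precursor_refs = toy$references$precursor,
    mature_link = toy$references$mature_link,
    priority = config$priority, pirna_band = config$pirna_band,
    pirna_require_unannotated = config$pirna_require_unannotated,
    conserved_matches = cons_matches)
  rec0 <- do.call(annotate_cascade, cascade_args)

  say("discover: novel miRNA prediction")
  cand_ids <- rec0$tag_id[rec0$category %in% c("piRNA", "unannotated")]
  cand_tags <- tags[tags$tag_id %in% cand_ids &
                      tags$tag_id %in% genome_hits$tag_id, , drop = FALSE]
  novel <- discover_novel(cand_tags, toy$genome, gindex,
                          params = config$discovery)
  acc <- novel[novel$accepted, , drop = FALSE]
  novel_ids <- character(0)
  if (nrow(acc) > 0 && nrow(genome_hits) > 0) {
    ov <- vapply(seq_len(nrow(genome_hits)), function(i) {
      any(acc$ref == genome_hits$ref[i] &
            acc$precursor_start < genome_hits$end[i] &
            acc$precursor_end > genome_hits$start[i])
    }, logical(1))
    novel_ids <- unique(genome_hits$tag_id[ov])
  }

  say("annotate: final cascade with ", length(novel_ids),
      " novel-supported tags")
  rec <- do.call(annotate_cascade, c(cascade_args,
                                     list(novel_ids = novel_ids)))

  say("quant: expression and biogenesis statistics")
  count_mat <- as.matrix(tags[, STAGES])
  rownames(count_mat) <- tags$tag_id
  rpm <- rpm_normalize(count_mat, clean_totals[STAGES])

  # isomiR grouping also considers unannotated tags: variants with
  # non-templated 3' additions fail the perfect-precursor rule of the
  # conserved cascade but still belong to their parent's isomiR set
  mature_ann <- conserved_mature_annotation(toy)
  iso <- isomir_stats(
    tags[rec$category %in% c("miRNA_conserved", "unannotated"), ,
         drop = FALSE],
    toy$references$precursor, mature_ann)

  mirna_counts <- mirna_count_matrix(tags, rec, iso, acc)
  mirna_rpm <- rpm_normalize(mirna_counts, clean_totals[STAGES])
  spec_tab <- specificity_table(mirna_rpm, config$specificity_threshold)

  pairs <- list(c("ovary", "ovotestis"), c("ovotestis", "testis"),
                c("ovary", "testis"))
  de <- lapply(pairs, function(p) {
    cbind(id = rownames(mirna_counts),
          diff_expression(mirna_counts[, p[1]], mirna_counts[, p[2]],
                          clean_totals[[p[1]]], clean_totals[[p[2]]]),
          stringsAsFactors = FALSE)
  })
  names(de) <- vapply(pairs, paste, "", collapse = "_vs_")

  bias <- lapply(STAGES, function(s) first_nt_bias(tags, stage = s))
  names(bias) <- STAGES
  len_dist <- length_distribution(tags)

  arm <- rbind(
    conserved_arm_counts(tags, toy),
    if (nrow(acc) > 0) novel_arm_counts(tags, genome_hits, acc))
  arm <- arm_usage(arm)

  say("evo: families, clusters, consensus, phylogeny")
  mirna_loci <- mirna_locus_table(toy, acc)
  clusters <- detect_clusters(mirna_loci, max_gap = config$cluster_max_gap)
  cons_loci <- mirna_loci[mirna_loci$name %in%
                            names(toy$references$precursor), ,
                          drop = FALSE]
  cn <- if (nrow(cons_loci) > 0) {
    copy_number_table(data.frame(species = rep("synthetic",
                                               nrow(cons_loci)),
                                 name = cons_loci$name,
                                 stringsAsFactors = FALSE))
  } else {
    list(counts = data.frame(), per_species = data.frame())
  }
  cons <- list()
  if (length(toy$references$precursor) > 0) {
    fam <- parse_family(names(toy$references$precursor))
    cons <- lapply(split(names(toy$references$precursor), fam),
                   function(nm) {
      if (length(nm) < 2) return(NULL)
      sq <- toy$references$precursor[nm]
      if (length(unique(nchar(sq))) != 1) return(NULL)
      consensus_sequence(sq, config$consensus_case_threshold)
    })
    cons <- cons[!vapply(cons, is.null, logical(1))]
  }
  phylo <- NULL
  if (length(toy$references$precursor) >= 3 &&
      length(unique(nchar(toy$references$precursor))) == 1) {
    phylo <- bootstrap_support(toy$references$precursor,
                               n_replicates = config$bootstrap_replicates,
                               seed = config$seed + 7L)
  }

  say("scan-targets: seed sites in 3'UTRs")
  utr_feats <- toy$features[toy$features$class == "utr3", , drop = FALSE]
  utrs <- setNames(
    substr(toy$genome[utr_feats$contig], utr_feats$start + 1L,
           utr_feats$end),
    utr_feats$feature_id)
  neg <- utr_feats$strand == "-"
  if (any(neg)) utrs[neg] <- revcomp(utrs[neg])
  matures <- c(toy$references$mature,
               setNames(acc$mature_seq, acc$candidate_id))
  sites <- scan_all_targets(utrs, matures)

  manifest <- list(
    package_version = as.character(utils::packageVersion("srnaflow")),
    seed = config$seed, spec_seed = config$spec$rng_seed,
    params = list(discovery = unclass(config$discovery),
                  priority = config$priority,
                  pirna_band = config$pirna_band,
                  min_len = config$min_len, max_len = config$max_len),
    tallies = list(
      raw_reads = vapply(sim$libraries, nrow, integer(1)),
      discard = lapply(cleaned, function(x) as.list(x$tally)),
      clean_reads = clean_totals,
      unique_tags = nrow(tags),
      categories = as.list(table(rec$category)),
      novel_candidates = nrow(novel), novel_accepted = nrow(acc)),
    conservation = list(
      reads_balanced = all(vapply(names(sim$libraries), function(s) {
        tl <- cleaned[[s]]$tally
        sum(tl[DISCARD_RULES]) + tl[["clean"]] == nrow(sim$libraries[[s]])
      }, logical(1))),
      tags_partitioned = nrow(rec) == nrow(tags) &&
        sum(table(rec$category)) == nrow(tags),
      rpm_sums = colSums(rpm)))

  res <- structure(list(
    config = config, toy = toy, sim = sim, cleaned = cleaned,
    tags = tags, genome_hits = genome_hits, annotation = rec,
    novel = novel, expression = list(counts = mirna_counts,
                                     rpm = mirna_rpm,
                                     specificity = spec_tab),
    tag_rpm = rpm, de = de, isomir = iso, bias = bias,
    length_dist = len_dist, arm_usage = arm, clusters = clusters,
    copy_number = cn, consensus = cons, phylo = phylo, sites = sites,
    pirna = pirna_stage_sets(tags, rec),
    manifest = manifest), class = "srnaflow_result")

  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  say(sprintf("done in %.1f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

# mature-arm annotation table for the conserved reference set (star
# entries are reference sequences, not isomiR parents)
conserved_mature_annotation <- function(toy) {
  nms <- names(toy$references$precursor)
  if (length(nms) == 0L) {
    return(data.frame(mature_id = character(0),
                      precursor_id = character(0),
                      mature_start = integer(0), mature_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(nms, function(nm) {
    hp <- toy$hairpins[[nm]]
    data.frame(mature_id = nm, precursor_id = nm,
               mature_start = hp$m_start, mature_end = hp$m_end,
               stringsAsFactors = FALSE)
  }))
}

# per-miRNA count matrix: conserved miRNAs (isomiR member counts summed)
# plus accepted novel matures (their tag counts)
mirna_count_matrix <- function(tags, rec, iso, acc) {
  rows <- list()
  if (nrow(iso$members) > 0) {
    for (mid in sort(unique(iso$members$mature_id))) {
      m <- iso$members[iso$members$mature_id == mid, , drop = FALSE]
      rows[[mid]] <- vapply(STAGES, function(s) sum(m[[s]]), numeric(1))
    }
  }
  if (nrow(acc) > 0) {
    for (i in seq_len(nrow(acc))) {
      t <- tags[tags$seq == acc$mature_seq[i], , drop = FALSE]
      if (nrow(t) == 0) next
      rows[[acc$candidate_id[i]]] <-
        vapply(STAGES, function(s) sum(t[[s]]), numeric(1))
    }
  }
  if (length(rows) == 0) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, STAGES)))
  }
  do.call(rbind, rows)
}

# arm read counts for conserved precursors, by substring position
conserved_arm_counts <- function(tags, toy) {
  prec <- toy$references$precursor
  if (length(prec) == 0) {
    return(data.frame(precursor_id = character(0), count_5p = numeric(0),
                      count_3p = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(names(prec), function(nm) {
    hp <- toy$hairpins[[nm]]
    mid_loop <- (hp$m_end + hp$s_start) / 2
    c5 <- 0; c3 <- 0
    for (i in seq_len(nrow(tags))) {
      pos <- as.integer(regexpr(tags$seq[i], prec[[nm]],
                                fixed = TRUE)) - 1L
      if (pos < 0) next
      center <- pos + tags$length[i] / 2
      if (center < mid_loop) c5 <- c5 + tags$total_count[i] else
        c3 <- c3 + tags$total_count[i]
    }
    data.frame(precursor_id = nm, count_5p = c5, count_3p = c3,
               stringsAsFactors = FALSE)
  }))
}

# arm read counts for accepted novel candidates: each tag is assigned
# once, by its substring position on the oriented precursor (searching
# the precursor sequence itself avoids double-counting the mirrored
# minus-strand genome hit of a hairpin tag)
novel_arm_counts <- function(tags, genome_hits, acc) {
  do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
    arms <- sort(c(acc$mature_start[i], acc$mature_end[i],
                   acc$star_start[i], acc$star_end[i]))
    mid_loop <- (arms[2] + arms[3]) / 2
    c5 <- 0; c3 <- 0
    for (j in seq_len(nrow(tags))) {
      pos <- as.integer(regexpr(tags$seq[j], acc$precursor[i],
                                fixed = TRUE)) - 1L
      if (pos < 0) next
      center <- pos + tags$length[j] / 2
      if (center < mid_loop) c5 <- c5 + tags$total_count[j] else
        c3 <- c3 + tags$total_count[j]
    }
    data.frame(precursor_id = acc$candidate_id[i], count_5p = c5,
               count_3p = c3, stringsAsFactors = FALSE)
  }))
}

# locus table of all miRNA precursors (conserved planted + accepted novel)
mirna_locus_table <- function(toy, acc) {
  f <- toy$features
  cons <- f[f$class == "conserved_hairpin", , drop = FALSE]
  out <- data.frame(name = cons$feature_id, contig = cons$contig,
                    start = cons$start, end = cons$end,
                    strand = cons$strand, stringsAsFactors = FALSE)
  if (nrow(acc) > 0) {
    out <- rbind(out, data.frame(
      name = acc$candidate_id, contig = acc$ref,
      start = acc$precursor_start, end = acc$precursor_end,
      strand = acc$strand, stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.srnaflow_result <- function(x, ...) {
  m <- x$manifest
  cat("srnaflow pipeline result\n")
  cat("  raw reads:   ", paste(m$tallies$raw_reads, collapse = " / "),
      " (", paste(names(m$tallies$raw_reads), collapse = " / "), ")\n",
      sep = "")
  cat("  clean reads: ", paste(m$tallies$clean_reads, collapse = " / "),
      "\n", sep = "")
  cat("  unique tags: ", m$tallies$unique_tags, "\n", sep = "")
  cat("  categories:\n")
  for (nm in names(m$tallies$categories)) {
    cat(sprintf("    %-18s %d\n", nm, m$tallies$categories[[nm]]))
  }
  cat("  novel miRNAs accepted: ", m$tallies$novel_accepted, " of ",
      m$tallies$novel_candidates, " candidate loci\n", sep = "")
  invisible(x)
}

# write every tabular/sequence output of a run
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_toy_genome(res$toy, dir)
  for (s in names(res$sim$libraries)) {
    lib <- res$sim$libraries[[s]]
    x <- Biostrings::DNAStringSet(lib$seq)
    names(x) <- lib$id
    Biostrings::writeXStringSet(x, file.path(dir, paste0(s, ".fastq")),
                                format = "fastq",
                                qualities = Biostrings::BStringSet(lib$qual))
  }
  write_tsv(res$sim$truth, file.path(dir, "truth.tsv"))
  write_tags(res$tags, file.path(dir, "tags.fa"),
             file.path(dir, "tags.tsv"))
  write_tsv(res$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(res$novel, file.path(dir, "novel_candidates.tsv"))
  acc <- res$novel[res$novel$accepted, , drop = FALSE]
  if (nrow(acc) > 0) {
    write_fasta(setNames(acc$precursor, acc$candidate_id),
                file.path(dir, "novel_precursors.fa"))
    write_gff3(data.frame(feature_id = acc$candidate_id,
                          class = "novel_miRNA", contig = acc$ref,
                          start = acc$precursor_start,
                          end = acc$precursor_end, strand = acc$strand),
               file.path(dir, "novel_loci.gff3"))
  }
  em <- data.frame(id = rownames(res$expression$rpm),
                   res$expression$rpm, check.names = FALSE)
  write_tsv(em, file.path(dir, "expression_rpm.tsv"))
  write_tsv(res$expression$specificity,
            file.path(dir, "specificity.tsv"))
  for (nm in names(res$de)) {
    write_tsv(res$de[[nm]], file.path(dir, paste0("de_", nm, ".tsv")))
  }
  write_tsv(res$isomir$members, file.path(dir, "isomirs.tsv"))
  for (s in names(res$bias)) {
    b <- data.frame(length = rownames(res$bias[[s]]), res$bias[[s]],
                    check.names = FALSE)
    write_tsv(b, file.path(dir, paste0("first_nt_", s, ".tsv")))
  }
  ld <- data.frame(length = rownames(res$length_dist), res$length_dist,
                   check.names = FALSE)
  write_tsv(ld, file.path(dir, "length_distribution.tsv"))
  write_tsv(res$arm_usage, file.path(dir, "arm_usage.tsv"))
  write_tsv(res$clusters, file.path(dir, "clusters.tsv"))
  write_tsv(res$copy_number$counts, file.path(dir, "copy_number.tsv"))
  if (length(res$consensus) > 0) {
    write_tsv(data.frame(family = names(res$consensus),
                         consensus = unlist(res$consensus)),
              file.path(dir, "consensus.tsv"))
  }
  if (!is.null(res$phylo)) {
    ape::write.tree(res$phylo$tree, file.path(dir, "nj_tree.nwk"))
  }
  write_tsv(res$sites, file.path(dir, "target_sites.tsv"))
  write_sites_bed(res$sites, file.path(dir, "target_sites.bed"))
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
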