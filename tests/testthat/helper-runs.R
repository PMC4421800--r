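# Shared pipeline runs, built once per session and reused across files.

.run_cache <- new.env(parent = emptyenv())

# small genome + scaled-down libraries for fast unit/integration tests
mini_config <- function(seed = 7L) {
  pipeline_config(
    spec = genome_spec(
      n_novel_hairpins = 5L, n_conserved_hairpins = 3L,
      n_pirna_clusters = 1L,
      n_decoy_ncrnas = c(rRNA = 1L, tRNA = 1L, snRNA = 1L, snoRNA = 1L),
      n_gene_models = 1L, n_repeats = 1L,
      decoy_reasons = c("free_energy", "min_pairs", "mature_length",
                        "cut_depth"),
      rng_seed = seed),
    seed = seed, bootstrap_replicates = 20L)
}

mini_profiles <- function(toy) {
  profs <- default_profiles(toy)
  lapply(profs, function(p) {
    p$abundance[grepl("^pirna_cluster", names(p$abundance))] <- 150
    p
  })
}

get_mini_run <- function() {
  if (is.null(.run_cache$mini)) {
    cfg <- mini_config()
    toy <- build_toy_genome(cfg$spec)
    .run_cache$mini <- run_pipeline(cfg, profiles = mini_profiles(toy),
                                    quiet = TRUE)
  }
  .run_cache$mini
}

# full default study conditions (20 planted hairpins, 10 decoys)
get_default_run <- function() {
  if (is.null(.run_cache$default)) {
    .run_cache$default <- run_pipeline(
      pipeline_config(spec = genome_spec(rng_seed = 2024L), seed = 11L),
      quiet = TRUE)
  }
  .run_cache$default
}

# map accepted novel candidates onto planted features by locus overlap
match_planted <- function(novel, features, classes) {
  planted <- features[features$class %in% classes, , drop = FALSE]
  vapply(seq_len(nrow(novel)), function(i) {
    ov <- planted$feature_id[planted$contig == novel$ref[i] &
                               planted$start < novel$precursor_end[i] &
                               planted$end > novel$precursor_start[i]]
    if (length(ov) == 0) NA_character_ else ov[1]
  }, character(1))
}
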