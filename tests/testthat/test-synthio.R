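small_spec <- function(seed = 3L) {
  genome_spec(n_novel_hairpins = 3L, n_conserved_hairpins = 2L,
              n_pirna_clusters = 1L,
              n_decoy_ncrnas = c(rRNA = 1L, tRNA = 1L, snRNA = 0L,
                                 snoRNA = 0L),
              n_gene_models = 1L, n_repeats = 1L,
              decoy_reasons = c("free_energy", "mature_length"),
              rng_seed = seed)
}

test_that("identical spec and seed give byte-identical genome and libraries", {
  a <- build_toy_genome(small_spec())
  b <- build_toy_genome(small_spec())
  expect_identical(a$genome, b$genome)
  expect_identical(a$features, b$features)
  sa <- simulate_libraries(a)
  sb <- simulate_libraries(b)
  expect_identical(sa$libraries, sb$libraries)
  expect_identical(sa$truth, sb$truth)
})

test_that("a spec with zero features yields a random genome and empty annotation", {
  spec <- genome_spec(n_novel_hairpins = 0L, n_conserved_hairpins = 0L,
                      n_pirna_clusters = 0L,
                      n_decoy_ncrnas = c(rRNA = 0L, tRNA = 0L,
                                         snRNA = 0L, snoRNA = 0L),
                      n_gene_models = 0L, n_repeats = 0L,
                      decoy_reasons = character(0),
                      genome_length = 5000L, rng_seed = 1L)
  toy <- build_toy_genome(spec)
  expect_equal(nchar(toy$genome[[1]]), 5000L)
  expect_equal(nrow(toy$features), 0L)
})

test_that("an explicit genome length too small for the features errors", {
  spec <- small_spec()
  spec$genome_length <- 500L
  expect_error(build_toy_genome(spec), "capacity")
})

test_that("every planted hairpin satisfies the discovery criteria checker", {
  toy <- build_toy_genome(small_spec(seed = 9L))
  planted <- names(toy$hairpins)[vapply(toy$hairpins, function(h) {
    h$class %in% c("novel_hairpin", "conserved_hairpin")
  }, logical(1))]
  for (nm in planted) {
    hp <- toy$hairpins[[nm]]
    cand <- srnaflow:::planted_candidate(hp$precursor, hp$m_start,
                                         hp$m_end, depth = 30L,
                                         copies = 1L)
    ev <- evaluate_precursor_criteria(cand, discovery_params())
    expect_true(ev$accept, label = nm)
  }
})

test_that("each decoy hairpin violates exactly its designated criterion", {
  toy <- build_toy_genome(small_spec(seed = 9L))
  dec <- toy$features[toy$features$class == "decoy_hairpin", ]
  for (i in seq_len(nrow(dec))) {
    hp <- toy$hairpins[[dec$feature_id[i]]]
    depth <- if (dec$decoy_reason[i] == "cut_depth") 2L else 30L
    copies <- if (dec$decoy_reason[i] == "max_copies") 22L else 1L
    cand <- srnaflow:::planted_candidate(hp$precursor, hp$m_start,
                                         hp$m_end, depth, copies)
    ev <- evaluate_precursor_criteria(cand, discovery_params())
    expect_false(ev$accept)
    expect_identical(ev$reasons, dec$decoy_reason[i])
  }
})

test_that("requested abundances are realised exactly, plus noise reads", {
  toy <- build_toy_genome(small_spec())
  profs <- default_profiles(toy)
  sim <- simulate_libraries(toy, profs)
  for (p in profs) {
    tr <- sim$truth[sim$truth$stage == p$stage, ]
    by_src <- table(tr$source)
    for (src in names(p$abundance)) {
      want <- as.integer(round(p$abundance[[src]]))
      got <- if (src %in% names(by_src)) as.integer(by_src[[src]]) else 0L
      expect_equal(got, want, label = paste(p$stage, src))
    }
    n_feat <- sum(tr$source != "noise")
    n_noise <- sum(tr$source == "noise")
    expect_equal(n_noise, as.integer(round(
      p$noise_read_fraction * n_feat / (1 - p$noise_read_fraction))))
  }
})

test_that("zero-jitter miRNA abundance yields identical inserts", {
  toy <- build_toy_genome(small_spec())
  profs <- default_profiles(toy)
  nov <- toy$features$feature_id[toy$features$class == "novel_hairpin"][1]
  tr <- simulate_libraries(toy, profs)$truth
  ins <- tr$insert[tr$source == nov]
  expect_gt(length(ins), 0)
  expect_equal(length(unique(ins)), 1L)
  expect_equal(unique(ins), toy$hairpins[[nov]]$mature)
})

test_that("piRNA 5'-U enforcement is exact at probability 1 and absent at 0", {
  toy <- build_toy_genome(small_spec())
  for (prob in c(1, 0)) {
    profs <- lapply(default_profiles(toy), function(p) {
      p$pirna_first_u_prob <- prob
      p
    })
    tr <- simulate_libraries(toy, profs)$truth
    first <- substr(tr$insert[tr$class == "pirna_cluster"], 1, 1)
    if (prob == 1) expect_true(all(first == "T")) else
      expect_true(all(first != "T"))
  }
})

test_that("raw reads are 50 nt with the adapter directly after the insert", {
  toy <- build_toy_genome(small_spec())
  sim <- simulate_libraries(toy)
  lib <- sim$libraries$ovary
  expect_true(all(nchar(lib$seq) == 50))
  tr <- sim$truth[sim$truth$stage == "ovary", ]
  i <- which(tr$length <= 28)[1]
  expect_equal(substr(lib$seq[i], 1, tr$length[i]), tr$insert[i])
  expect_equal(substr(lib$seq[i], tr$length[i] + 1, tr$length[i] + 6),
               substr(srnaflow:::DEFAULT_ADAPTER3, 1, 6))
})

test_that("abundance for an unknown feature errors with its name", {
  toy <- build_toy_genome(small_spec())
  profs <- default_profiles(toy)
  profs[[1]]$abundance[["no_such_feature"]] <- 5
  expect_error(simulate_libraries(toy, profs), "no_such_feature")
})
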