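test_that("candidate windows are extended, clipped and strand-oriented", {
  set.seed(11)
  g <- c(chr = rand_seq(10000))
  hits <- data.frame(ref = "chr", start = 500L, end = 522L, strand = "+",
                     stringsAsFactors = FALSE)
  w <- extract_candidate_windows(hits, g, flank = 100)
  expect_equal(w$win_start, 400L)
  expect_equal(w$win_end, 622L)
  expect_equal(w$tag_offset, 100L)
  expect_equal(substr(w$window, 101, 122), unname(substr(g, 501, 522)))

  # clipping at the contig start
  hits2 <- data.frame(ref = "chr", start = 30L, end = 52L, strand = "+",
                      stringsAsFactors = FALSE)
  w2 <- extract_candidate_windows(hits2, g, flank = 100)
  expect_equal(w2$win_start, 0L)
  expect_equal(w2$tag_offset, 30L)

  # minus-strand windows carry the reverse complement and mirrored offset
  hits3 <- data.frame(ref = "chr", start = 500L, end = 522L, strand = "-",
                      stringsAsFactors = FALSE)
  w3 <- extract_candidate_windows(hits3, g, flank = 100)
  expect_equal(w3$window, revcomp(w$window))
  expect_equal(substr(w3$window, w3$tag_offset + 1, w3$tag_offset + 22),
               revcomp(substr(g, 501, 522)))
})

test_that("duplex metrics match their definitions on explicit structures", {
  # perfect 20-bp duplex with a 10-nt loop
  m <- "GCGCGCGCGCATATATATGC"
  p <- paste0(m, strrep("A", 10), revcomp(m))
  fr <- fold(p)
  d <- evaluate_duplex(fr, c(0L, 20L), c(30L, 50L))
  expect_equal(d$pairs, 20L)
  expect_equal(d$bulge, 0L)
  expect_equal(d$asymmetry, 0L)
  expect_equal(d$loop_space, 10L)

  # a 3-nt bulge on the star arm only: bulge 3, asymmetry 3
  core <- "GCGGCGCGGCCGGCGC"
  rc <- revcomp(core)
  star <- paste0(substr(rc, 1, 8), "AAA", substr(rc, 9, 16))
  p2 <- paste0(core, strrep("A", 10), star)
  fr2 <- fold(p2)
  d2 <- evaluate_duplex(fr2, c(0L, 16L),
                        c(26L, 26L + nchar(star)))
  expect_equal(d2$pairs, 16L)
  expect_equal(d2$bulge, 3L)
  expect_equal(d2$asymmetry, 3L)

  expect_error(evaluate_duplex(fr, c(0L, 20L), c(10L, 30L)), "overlap")
})

test_that("duplex metrics equal an independent structure walk", {
  set.seed(12)
  for (k in 1:15) {
    m <- rand_seq(20)
    p <- paste0(m, strrep("A", 8), revcomp(m))
    fr <- fold(p)
    mature <- c(0L, 20L)
    star <- c(28L, 48L)
    d <- evaluate_duplex(fr, mature, star)
    # oracle: walk the pair vector directly
    partner <- fr$pairs
    m_idx <- 1:20
    s_idx <- 29:48
    paired <- !is.na(partner[m_idx]) & partner[m_idx] %in% s_idx
    expect_equal(d$pairs, sum(paired))
    if (sum(paired) > 0) {
      span <- range(which(paired))
      inside <- paired[span[1]:span[2]]
      runs <- rle(!inside)
      want_bulge_m <- if (any(runs$values))
        max(runs$lengths[runs$values]) else 0L
      s_paired <- !is.na(partner[s_idx]) & partner[s_idx] %in% m_idx
      span_s <- range(which(s_paired))
      inside_s <- s_paired[span_s[1]:span_s[2]]
      runs_s <- rle(!inside_s)
      want_bulge_s <- if (any(runs_s$values))
        max(runs_s$lengths[runs_s$values]) else 0L
      expect_equal(d$bulge, max(want_bulge_m, want_bulge_s))
      expect_equal(d$asymmetry, abs(sum(!inside) - sum(!inside_s)))
    }
  }
})

test_that("each criterion bound rejects with its own reason", {
  base <- list(mature_length = 22L, depth = 10L, copies = 1L,
               delta_g = -30,
               duplex = list(pairs = 20L, bulge = 0L, asymmetry = 0L,
                             loop_space = 10L))
  p <- discovery_params()
  expect_true(evaluate_precursor_criteria(base, p)$accept)

  cases <- list(
    list(mod = list(delta_g = -17.5), reason = "free_energy"),
    list(mod = list(duplex = modifyList(base$duplex, list(pairs = 13L))),
         reason = "min_pairs"),
    list(mod = list(mature_length = 17L), reason = "mature_length"),
    list(mod = list(mature_length = 27L), reason = "mature_length"),
    list(mod = list(depth = 2L), reason = "cut_depth"),
    list(mod = list(copies = 21L), reason = "max_copies"),
    list(mod = list(duplex = modifyList(base$duplex,
                                        list(loop_space = 36L))),
         reason = "max_loop"),
    list(mod = list(duplex = modifyList(base$duplex, list(bulge = 5L))),
         reason = "max_bulge"),
    list(mod = list(duplex = modifyList(base$duplex,
                                        list(asymmetry = 6L))),
         reason = "max_asymmetry"))
  for (cs in cases) {
    cand <- modifyList(base, cs$mod)
    ev <- evaluate_precursor_criteria(cand, p)
    expect_false(ev$accept)
    expect_identical(ev$reasons, cs$reason)
  }

  # multiple violations are all listed
  cand <- modifyList(base, list(delta_g = -10, depth = 1L))
  ev <- evaluate_precursor_criteria(cand, p)
  expect_setequal(ev$reasons, c("free_energy", "cut_depth"))
})

test_that("discovery on a mini genome recovers planted and rejects decoys", {
  res <- get_mini_run()
  f <- res$toy$features
  acc <- res$novel[res$novel$accepted, ]
  planted <- f[f$class == "novel_hairpin", ]
  for (i in seq_len(nrow(planted))) {
    expect_true(any(acc$ref == planted$contig[i] &
                      acc$precursor_start < planted$end[i] &
                      acc$precursor_end > planted$start[i]),
                label = planted$feature_id[i])
  }
  dec <- f[f$class == "decoy_hairpin", ]
  for (g in unique(dec$group)) {
    d <- dec[dec$group == g, ]
    rows <- res$novel[res$novel$ref == d$contig[1] &
                        res$novel$precursor_start < max(d$end) &
                        res$novel$precursor_end > min(d$start), ]
    expect_gt(nrow(rows), 0)
    expect_false(any(rows$accepted), label = g)
    expect_true(all(rows$reasons == d$decoy_reason[1]), label = g)
  }
})

test_that("a mature supported below the depth threshold is rejected", {
  res <- get_mini_run()
  dec <- res$toy$features[res$toy$features$decoy_reason %in% "cut_depth", ]
  rows <- res$novel[res$novel$ref == dec$contig[1] &
                      res$novel$precursor_start < dec$end[1] &
                      res$novel$precursor_end > dec$start[1], ]
  expect_true(all(rows$depth < 3))
  expect_true(all(rows$reasons == "cut_depth"))
})
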