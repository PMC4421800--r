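ADAPTER <- "TCGTATGCCGTCTTCTGCTTG"

mk_read <- function(insert, id = "r1", adapter = ADAPTER) {
  data.frame(id = id, seq = substr(paste0(insert, adapter, strrep("A", 50)),
                                   1, 50),
             qual = strrep("I", 50), stringsAsFactors = FALSE)
}

test_that("each discard rule fires on its construction and is tallied", {
  set.seed(1)
  ok <- rand_seq(22)
  reads <- rbind(
    mk_read(ok, "clean"),
    mk_read(rand_seq(16), "short"),                     # < 18 nt
    data.frame(id = "noad", seq = substr(paste0(rand_seq(26),
                                                strrep("C", 50)), 1, 50),
               qual = strrep("I", 50)),                 # no 3' adapter
    mk_read(strrep("A", 22), "polya"),
    mk_read(rand_seq(40), "long"),                      # > max_len
    data.frame(id = "lowq",
               seq = substr(paste0(rand_seq(22), ADAPTER,
                                   strrep("A", 50)), 1, 50),
               qual = strrep("#", 50)),                 # mean Phred ~2
    data.frame(id = "a5", seq = substr(paste0("GTTCAG", rand_seq(20),
                                              ADAPTER, strrep("A", 50)),
                                       1, 50),
               qual = strrep("I", 50))                  # 5' adapter start
  )
  res <- filter_and_trim(reads, adapter3 = ADAPTER, max_len = 32)
  expect_equal(res$clean$id, "clean")
  expect_equal(res$clean$insert, ok)
  t <- res$tally
  expect_equal(unname(t["too_short"]), 1L)
  expect_equal(unname(t["adapter3_missing"]), 1L)
  expect_equal(unname(t["poly_a"]), 1L)
  expect_equal(unname(t["inserted_fragment"]), 1L)
  expect_equal(unname(t["low_quality"]), 1L)
  expect_equal(unname(t["adapter5_contamination"]), 1L)
  # discard tally + clean = raw
  expect_equal(sum(t[srnaflow:::DISCARD_RULES]) + unname(t["clean"]),
               nrow(reads))
})

test_that("filtering is idempotent on already-clean reads", {
  set.seed(2)
  reads <- do.call(rbind, lapply(1:20, function(i) {
    mk_read(rand_seq(sample(18:28, 1)), paste0("r", i))
  }))
  r1 <- filter_and_trim(reads, adapter3 = ADAPTER)
  reread <- data.frame(id = r1$clean$id,
                       seq = substr(paste0(r1$clean$insert, ADAPTER,
                                           strrep("A", 50)), 1, 50),
                       qual = strrep("I", 50), stringsAsFactors = FALSE)
  r2 <- filter_and_trim(reread, adapter3 = ADAPTER)
  expect_equal(r2$clean$insert, r1$clean$insert)
  expect_equal(sum(r2$tally[srnaflow:::DISCARD_RULES]), 0L)
})

test_that("malformed records error with the record index", {
  reads <- data.frame(id = c("a", "b"), seq = c("ACGT", NA),
                      stringsAsFactors = FALSE)
  expect_error(filter_and_trim(reads, adapter3 = ADAPTER), "index 2")
})

test_that("collapsing conserves per-stage counts and merges across stages", {
  tags <- collapse_tags(list(ovary = c("ACGTACGTACGTACGTAA",
                                       "ACGTACGTACGTACGTAA",
                                       "TTTTACGTACGTACGTAC"),
                             testis = c("ACGTACGTACGTACGTAA")))
  expect_equal(nrow(tags), 2L)
  shared <- tags[tags$seq == "ACGTACGTACGTACGTAA", ]
  expect_equal(shared$ovary, 2L)
  expect_equal(shared$testis, 1L)
  expect_equal(shared$total_count, 3L)
  expect_equal(sum(tags$ovary), 3L)
  expect_equal(sum(tags$testis), 1L)
})

test_that("collapse conserves counts on a simulated library", {
  set.seed(3)
  inserts <- list(
    ovary = replicate(500, rand_seq(sample(18:30, 1))),
    ovotestis = replicate(300, rand_seq(sample(18:30, 1))),
    testis = replicate(200, rand_seq(sample(18:30, 1))))
  tags <- collapse_tags(inserts)
  for (s in names(inserts)) {
    expect_equal(sum(tags[[s]]), length(inserts[[s]]))
  }
  expect_equal(sum(tags$total_count), 1000L)
})
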