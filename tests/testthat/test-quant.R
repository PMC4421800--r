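test_that("RPM normalization is linear and conserves column sums", {
  m <- matrix(c(5, 0, 3, 2), nrow = 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  r <- rpm_normalize(m, totals = c(1e6, 5e5))
  expect_equal(r["a", "x"], 5)
  expect_equal(r["a", "y"], 6)
  # full tabulation: columns sum to 1e6
  set.seed(31)
  big <- matrix(rpois(300, 40), ncol = 3)
  rb <- rpm_normalize(big)
  expect_equal(unname(colSums(rb)), rep(1e6, 3), tolerance = 1e-9)
  expect_error(rpm_normalize(m, totals = c(0, 1)), "zero library total")
})

test_that("identical libraries give fold change 1 and p = 1", {
  d <- diff_expression(c(10, 25, 3), c(10, 25, 3), 1e4, 1e4)
  expect_equal(d$log2_fc, rep(0, 3))
  expect_true(all(d$p >= 0.95))
})

test_that("swapping libraries inverts fold change and keeps p", {
  set.seed(32)
  a <- rpois(30, 20); b <- rpois(30, 35)
  d1 <- diff_expression(a, b, 1e4, 2e4)
  d2 <- diff_expression(b, a, 2e4, 1e4)
  expect_equal(d1$log2_fc, -d2$log2_fc, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-9)
})

test_that("exact-test p equals the closed-form sum at small counts", {
  grid <- expand.grid(x = c(0, 1, 3, 10, 27, 50),
                      y = c(0, 2, 5, 18, 50),
                      na = c(1e4, 5e4), nb = c(1e4, 2e4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- srnaflow:::ac_exact_p(g$x, g$y, g$na, g$nb)
    want <- oracle_ac_p(g$x, g$y, g$na, g$nb)
    expect_equal(got, want, tolerance = 1e-8,
                 label = paste(g$x, g$y, g$na, g$nb))
  }
})

test_that("BH adjustment is monotone nondecreasing in rank order", {
  set.seed(33)
  p <- runif(100)^2
  d <- diff_expression(rpois(100, 10), rpois(100, 12), 1e4, 1e4)
  expect_true(all(d$padj >= d$p - 1e-12))
  ord <- order(d$p)
  expect_true(all(diff(d$padj[ord]) >= -1e-12))
})

test_that("specificity classes follow the presence pattern", {
  expect_equal(specificity_class(c(ovary = 10, ovotestis = 0,
                                   testis = 0)), "ovary")
  expect_equal(specificity_class(c(ovary = 10, ovotestis = 12,
                                   testis = 9)), "three-stage")
  expect_equal(specificity_class(c(ovary = 5, ovotestis = 0,
                                   testis = 3)), "ovary+testis")
  expect_equal(specificity_class(c(ovary = 0, ovotestis = 0,
                                   testis = 0)), "not_expressed")
})

test_that("isomiR grouping recovers offsets and non-templated additions", {
  set.seed(34)
  mature <- rand_seq(22)
  loop <- strrep("C", 12)
  prec <- paste0(mature, loop, revcomp(mature))
  ann <- data.frame(mature_id = "m1", precursor_id = "p1",
                    mature_start = 0L, mature_end = 22L,
                    stringsAsFactors = FALSE)
  variants <- c(mature,
                substr(prec, 1, 23),            # 3' +1 templated
                substr(prec, 2, 22),            # 5' +1
                paste0(mature, "G"))            # non-templated unless
  # ensure the G is truly non-templated (loop starts with C)
  tags <- data.frame(tag_id = paste0("t", 1:4), seq = variants,
                     length = nchar(variants),
                     ovary = c(50L, 5L, 3L, 2L),
                     ovotestis = c(40L, 0L, 0L, 0L),
                     testis = 0L,
                     total_count = c(90L, 5L, 3L, 2L),
                     stringsAsFactors = FALSE)
  iso <- isomir_stats(tags, c(p1 = prec), ann)
  expect_equal(nrow(iso$members), 4L)
  expect_equal(sort(iso$members$off3), c(0L, 0L, 0L, 1L))
  expect_equal(sort(iso$members$off5), c(0L, 0L, 0L, 1L))
  nta_row <- iso$members[iso$members$nta != "", ]
  expect_equal(nrow(nta_row), 1L)
  expect_equal(nta_row$nta, "G")
  expect_equal(nta_row$off3, 0L)
  # per-stage means: 4 variants in ovary / 1 miRNA; 1 in ovotestis
  expect_equal(unname(iso$mean_per_stage["ovary"]), 4)
  expect_equal(unname(iso$mean_per_stage["ovotestis"]), 1)
  expect_equal(unname(iso$mean_per_stage["testis"]), 0)
})

test_that("first-nucleotide bias rows sum to one and detect pure-U input", {
  tags <- data.frame(tag_id = c("a", "b"),
                     seq = c("TGCATGCATGCATGCATGCAT", "TTTTTTTTTTTTTTTTTTTTTT"),
                     length = c(21L, 22L), ovary = c(3L, 7L),
                     ovotestis = 0L, testis = 0L, total_count = c(3L, 7L),
                     stringsAsFactors = FALSE)
  b <- first_nt_bias(tags, stage = "ovary")
  expect_equal(unname(rowSums(b)), rep(1, nrow(b)))
  expect_equal(unname(b["21", "U"]), 1)
  expect_equal(unname(b["22", "U"]), 1)
})

test_that("arm usage labels follow read support and majority rule", {
  ac <- data.frame(precursor_id = c("p1", "p2", "p3", "p4"),
                   count_5p = c(100, 0, 100, 20),
                   count_3p = c(8, 40, 0, 20),
                   stringsAsFactors = FALSE)
  u <- arm_usage(ac)
  expect_equal(u$label, c("both", "3p", "5p", "both"))
  expect_equal(u$guide, c("5p", "3p", "5p", "co-dominant"))
  expect_equal(u$star[1], "3p")
})
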