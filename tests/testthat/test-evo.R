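test_that("family parsing strips paralog letters, copy suffixes and prefixes", {
  expect_equal(parse_family(c("mir-92a", "mir-92b")),
               c("miR-92", "miR-92"))
  expect_equal(parse_family(c("miR-19b-1", "miR-19b-2")),
               c("miR-19", "miR-19"))
  expect_equal(parse_family("miR-7"), "miR-7")
  expect_equal(parse_family("dre-miR-430c-2"), "miR-430")
  expect_equal(parse_family("hsa-let-7a"), "let-7")
  expect_warning(fam <- parse_family("oddname"), "unparseable")
  expect_equal(fam, "oddname")
})

test_that("copy-number tables partition single and multiple copies", {
  loci <- data.frame(
    species = c(rep("sp1", 4), rep("sp2", 3)),
    name = c("miR-1", "miR-92a", "miR-92b", "miR-92c",
             "miR-1", "miR-7a", "miR-7b"),
    stringsAsFactors = FALSE)
  ct <- copy_number_table(loci)
  sp1 <- ct$per_species[ct$per_species$species == "sp1", ]
  expect_equal(sp1$n_families, 2L)
  expect_equal(sp1$single_fraction, 0.5)
  expect_equal(sp1$multi_fraction, 0.5)
  expect_equal(ct$counts$copies[ct$counts$species == "sp1" &
                                  ct$counts$family == "miR-92"], 3L)
  # conserved = present in >= 2 species
  expect_true(all(ct$counts$conserved[ct$counts$family == "miR-1"]))
  expect_false(any(ct$counts$conserved[ct$counts$family == "miR-92"]))
  # a heavily duplicated family is counted in full
  big <- data.frame(species = "sp3",
                    name = sprintf("miR-430-%d", 1:78),
                    stringsAsFactors = FALSE)
  ct2 <- copy_number_table(big)
  expect_equal(ct2$counts$copies, 78L)
  expect_equal(ct2$per_species$multi_fraction, 1)
})

test_that("cluster chaining joins near loci and is order-invariant", {
  loci <- data.frame(
    name = sprintf("m%d", 1:8),
    contig = "chr7",
    start = c(0, 100, 220, 340, 460, 580, 700, 820) * 1L,
    end = c(80, 180, 300, 420, 540, 660, 780, 900) * 1L,
    stringsAsFactors = FALSE)
  cl <- detect_clusters(loci, max_gap = 10000)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 8L)
  expect_equal(cl$span, 900L)
  expect_equal(cl$members, paste(sprintf("m%d", 1:8), collapse = ","))

  far <- data.frame(name = c("a", "b"), contig = "chr1",
                    start = c(0L, 60000L), end = c(80L, 60080L),
                    stringsAsFactors = FALSE)
  cl2 <- detect_clusters(far, max_gap = 10000)
  expect_equal(nrow(cl2), 2L)
  expect_true(all(cl2$n_members == 1L))

  # order invariance and equality with brute-force chaining
  set.seed(41)
  rnd <- data.frame(name = sprintf("x%02d", 1:30), contig = "c",
                    start = sort(sample.int(2e5, 30)),
                    stringsAsFactors = FALSE)
  rnd$end <- rnd$start + 70L
  shuf <- rnd[sample.int(30), ]
  c1 <- detect_clusters(rnd, max_gap = 5000)
  c2 <- detect_clusters(shuf, max_gap = 5000)
  expect_equal(c1$members, c2$members)
  # brute force: walk sorted loci accumulating chains
  chains <- list(); cur <- rnd$name[1]; last_end <- rnd$end[1]
  for (i in 2:nrow(rnd)) {
    if (rnd$start[i] - last_end <= 5000) {
      cur <- c(cur, rnd$name[i])
    } else {
      chains[[length(chains) + 1]] <- cur; cur <- rnd$name[i]
    }
    last_end <- max(last_end, rnd$end[i])
  }
  chains[[length(chains) + 1]] <- cur
  expect_equal(c1$members,
               vapply(chains, paste, "", collapse = ","))
})

test_that("consensus applies modal bases with case-coded conservation", {
  expect_equal(consensus_sequence(rep("ACGU", 5)), "ACGU")
  seqs <- c(rep("UAUU", 6), rep("AAUU", 4))
  expect_equal(consensus_sequence(seqs, case_threshold = 0.9), "uAUU")
  expect_equal(consensus_sequence(seqs, case_threshold = 0.5), "UAUU")
  # ties resolve by fixed base order (A before C) at both positions
  tie <- c("AC", "CA", "AC", "CA")
  expect_equal(consensus_sequence(tie, case_threshold = 0.9), "aa")
  expect_error(consensus_sequence(character(0)), "empty")
  # idempotence: consensus of the consensus is itself (case-stripped)
  cs <- consensus_sequence(seqs, 0.9)
  expect_equal(consensus_sequence(toupper(cs), 0.9), toupper(cs))
})

test_that("p-distances count mismatches over pairwise-deleted sites", {
  al <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TCGTACGTAA")
  d <- p_distance_matrix(al)
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 0.2)
  expect_equal(d, t(d))
  gap <- c(a = "AC-TAC", b = "ACGTAC")
  dg <- p_distance_matrix(gap)
  expect_equal(unname(dg["a", "b"]), 0)
  allgap <- c(a = "---A", b = "AAA-")
  expect_error(p_distance_matrix(allgap), "zero comparable")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  # three-point formulas: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.6 - 0.3) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
})

test_that("NJ recovers random additive trees exactly (spot check)", {
  set.seed(42)
  for (k in 1:10) {
    n <- sample(4:10, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(x) runif(x, 0.05, 1))
    d <- cophenetic(true)
    rec <- nj_tree(d[true$tip.label, true$tip.label])
    expect_equal(as.numeric(ape::dist.topo(true, rec)), 0)
    expect_equal(cophenetic(rec)[true$tip.label, true$tip.label],
                 d[true$tip.label, true$tip.label], tolerance = 1e-8)
  }
})

test_that("bootstrap support is deterministic and bounded", {
  set.seed(43)
  base <- rand_seq(60)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(v), k)
    v[idx] <- sapply(v[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    })
    paste(v, collapse = "")
  }
  al <- c(t1 = base, t2 = mut(base, 2), t3 = mut(base, 12),
          t4 = mut(base, 25), t5 = mut(base, 30))
  b1 <- bootstrap_support(al, n_replicates = 50, seed = 99)
  b2 <- bootstrap_support(al, n_replicates = 50, seed = 99)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 1))
  # n = 1 gives only 0/1 supports
  b3 <- bootstrap_support(al, n_replicates = 1, seed = 5)
  expect_true(all(b3$support %in% c(0, 1)))
})
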