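# miRNA family and cluster evolution: name-based family grouping,
# copy-number tables across species, genomic cluster detection, consensus
# sequences with case coding, p-distances, neighbor-joining trees and
# bootstrap support.

#' Parse a miRNA precursor name into its family base name
#'
#' Duplicated miRNA genes are named as homolog groups: numeric copy
#' suffixes (`miR-n-1` ... `miR-n-n`) and single-letter paralog suffixes
#' (`miR-na`, `-nb`, ...) are stripped, as is any species prefix
#' (`dre-`, `hsa-`, ...). Case-insensitive; `let-` families are handled
#' like `miR-`.
#'
#' @param name character vector of precursor names.
#' @return character vector of family base names (`miR-17`, `let-7`, ...);
#'   unparseable names pass through with a warning.
#' @export
parse_family <- function(name) {
  vapply(name, function(nm) {
    m <- regmatches(nm, regexec(
      "(?i)(mir|let)-?([0-9]+)([a-z]*)((-[0-9]+)*)$", nm))[[1]]
    if (length(m) == 0L) {
      warning("unparseable miRNA name: ", nm)
      return(nm)
    }
    stem <- if (tolower(m[2]) == "let") "let" else "miR"
    paste0(stem, "-", m[3])
  }, character(1), USE.NAMES = FALSE)
}

#' Copy-number table of miRNA families per species
#'
#' Counts precursor loci per family and species, partitions families into
#' single- and multiple-copy, and marks families present in at least two
#' species as conserved.
#'
#' @param loci data.frame with `species` and `name` (precursor name)
#'   columns.
#' @return list with `counts` (data.frame species, family, copies,
#'   conserved), and `per_species` (data.frame species, n_families,
#'   single_fraction, multi_fraction, n_multi, n_multi_conserved).
#' @export
copy_number_table <- function(loci) {
  loci$family <- parse_family(loci$name)
  counts <- stats::aggregate(list(copies = loci$name),
                             by = list(species = loci$species,
                                       family = loci$family), FUN = length)
  n_species <- tapply(counts$species, counts$family,
                      function(s) length(unique(s)))
  counts$conserved <- n_species[counts$family] >= 2L
  per_species <- do.call(rbind, lapply(split(counts, counts$species),
    function(d) {
      data.frame(species = d$species[1L], n_families = nrow(d),
                 single_fraction = mean(d$copies == 1L),
                 multi_fraction = mean(d$copies > 1L),
                 n_multi = sum(d$copies > 1L),
                 n_multi_conserved = sum(d$copies > 1L & d$conserved),
                 stringsAsFactors = FALSE)
    }))
  rownames(per_species) <- NULL
  rownames(counts) <- NULL
  list(counts = counts, per_species = per_species)
}

#' Detect genomic miRNA clusters by single-linkage chaining
#'
#' Consecutive precursors on the same contig whose gap is at most
#' `max_gap` form one cluster. Invariant to input ordering.
#'
#' @param loci data.frame with `name`, `contig`, `start`, `end` (0-based
#'   half-open) and optional `strand`.
#' @param max_gap maximum gap between consecutive members, bp (default
#'   10 kb).
#' @return data.frame with one row per cluster: `cluster_id`, `contig`,
#'   `start`, `end`, `span`, `n_members`, `members` (comma-separated, in
#'   genomic order).
#' @export
detect_clusters <- function(loci, max_gap = 10000L) {
  out <- list()
  cid <- 0L
  for (ctg in sort(unique(loci$contig))) {
    d <- loci[loci$contig == ctg, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      d$start[-1L] - cummax(d$end[-nrow(d)]) > max_gap)))
    for (g in split(d, grp)) {
      cid <- cid + 1L
      out[[cid]] <- data.frame(
        cluster_id = sprintf("cluster_%03d", cid), contig = ctg,
        start = min(g$start), end = max(g$end),
        span = max(g$end) - min(g$start), n_members = nrow(g),
        members = paste(g$name, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cluster_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      span = integer(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Consensus sequence of homologs with conservation case coding
#'
#' Per position, the modal base; uppercase iff its frequency reaches the
#' case threshold, lowercase otherwise. Ties are broken by fixed base
#' order (A < C < G < U/T < gap). Input sequences must be pre-aligned
#' (equal length); the consensus is reported in RNA letters.
#'
#' @param seqs character vector of equal-length sequences.
#' @param case_threshold uppercase threshold on modal frequency (default
#'   0.9).
#' @return consensus string with case coding.
#' @export
consensus_sequence <- function(seqs, case_threshold = 0.9) {
  if (length(seqs) == 0L) stop("empty input")
  seqs <- as_dna(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must be pre-aligned (equal length)")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  order_bases <- c("A", "C", "G", "T", "-")
  cons <- vapply(seq_len(L), function(j) {
    tab <- table(factor(m[, j], levels = order_bases))
    b <- order_bases[which.max(tab)]     # which.max takes the first tie
    fr <- max(tab) / sum(tab)
    b <- chartr("T", "U", b)
    if (fr >= case_threshold) b else tolower(b)
  }, character(1))
  paste(cons, collapse = "")
}

#' Pairwise p-distance matrix from an alignment
#'
#' d(i, j) = mismatches / compared sites with pairwise deletion of gap
#' positions (`-` or `.`).
#'
#' @param aligned named character vector of equal-length aligned
#'   sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aligned) {
  n <- length(aligned)
  L <- unique(nchar(aligned))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(as_dna(aligned), "", fixed = TRUE))
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("zero comparable sites between ", names(aligned)[i], " and ",
             names(aligned)[j])
      }
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration; on an additive matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param d symmetric non-negative distance matrix (>= 3 taxa).
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix is not symmetric")
  ape::nj(stats::as.dist(d))
}

#' Bootstrap support for the internal edges of an alignment's NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance + neighbor-joining tree for each replicate, and reports for
#' each internal bipartition of the original tree the fraction of
#' replicate trees containing it. Deterministic under a fixed seed.
#'
#' @param aligned named character vector of aligned sequences.
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return list with `tree` (the original NJ tree) and `support` (numeric
#'   vector, one value in `[0, 1]` per internal node of the original
#'   tree).
#' @export
bootstrap_support <- function(aligned, n_replicates = 100L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  tree <- nj_tree(p_distance_matrix(aligned))
  L <- nchar(aligned[[1]])
  mat <- do.call(rbind, strsplit(as_dna(aligned), "", fixed = TRUE))
  rownames(mat) <- names(aligned)
  reps <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    nj_tree(p_distance_matrix(res))
  }))
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  list(tree = tree, support = counts / n_replicates)
}
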