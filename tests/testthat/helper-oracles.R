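# Independent oracles used across the suite. Each re-derives the quantity
# a package routine computes, by a different route (enumeration, direct
# summation, sliding-window scan), sharing at most the energy tables.

# ---- folding: exhaustive enumeration over hairpin-class structures ------
# Enumerates every nested chain of canonical pairs and scores each with
# structure_energy(); returns the minimum (0 if no negative structure).
enumerate_mfe <- function(sequence) {
  s <- strsplit(srnaflow::as_dna(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  can_pair <- function(i, j) {
    paste0(s[i], s[j]) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  # all chains whose outermost pair is (i, j), as lists of rbind-able rows
  memo <- new.env()
  chains_from <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- list()
    if (j - i - 1 >= 3) res[[1]] <- matrix(c(i, j), ncol = 2)
    if (j - i - 1 >= 2) {
      for (c in (i + 1):(j - 2)) {
        for (d in (c + 1):(j - 1)) {
          if (!can_pair(c, d)) next
          for (sub in chains_from(c, d)) {
            res[[length(res) + 1]] <- rbind(c(i, j), sub)
          }
        }
      }
    }
    memo[[key]] <- res
    res
  }
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!can_pair(i, j)) next
      for (ch in chains_from(i, j)) {
        e <- srnaflow::structure_energy(sequence, ch)
        if (e < best) best <- e
      }
    }
  }
  best
}

# ---- mapping: brute-force sliding-window Hamming scan -------------------
oracle_scan <- function(tag, references, max_mismatches) {
  enc <- function(x) {
    v <- match(strsplit(srnaflow::as_dna(x), "", fixed = TRUE)[[1]],
               c("A", "C", "G", "T"))
    v[is.na(v)] <- 9L
    v
  }
  out <- list()
  for (rid in names(references)) {
    rv <- enc(references[[rid]])
    n <- length(rv)
    for (str in c("+", "-")) {
      tv <- enc(if (str == "+") tag else srnaflow::revcomp(tag))
      w <- length(tv)
      if (w > n) next
      mm <- integer(n - w + 1)
      for (i in seq_len(w)) {
        mm <- mm + as.integer(rv[i:(n - w + i)] != tv[i] | tv[i] == 9L)
      }
      hit <- which(mm <= max_mismatches)
      if (length(hit) == 0) next
      out[[length(out) + 1]] <- data.frame(
        ref = rid, start = hit - 1L, end = hit - 1L + w, strand = str,
        mismatches = mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(ref = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mismatches, res$ref, res$start), ]
  rownames(res) <- NULL
  res
}

# ---- exact test: direct closed-form summation ---------------------------
# Conditional on n = x + y the count x follows Binomial(n, pr); the
# two-sided p sums every outcome no more probable than the observed one.
# Probabilities are evaluated from the factorial closed form directly.
oracle_ac_p <- function(x, y, n_a, n_b) {
  n <- x + y
  if (n == 0) return(1)
  pr <- n_a / (n_a + n_b)
  pmf <- function(k) {
    exp(lchoose(n, k) + k * log(pr) + (n - k) * log(1 - pr))
  }
  probs <- vapply(0:n, pmf, numeric(1))
  min(1, sum(probs[probs <= probs[x + 1] * (1 + 1e-7)]))
}

# ---- seed sites: per-offset window classification -----------------------
oracle_seed_sites <- function(utr, mature) {
  utr <- srnaflow::as_dna(utr); mature <- srnaflow::as_dna(mature)
  L <- nchar(utr)
  m6 <- srnaflow::revcomp(substr(mature, 2, 7))
  m7 <- srnaflow::revcomp(substr(mature, 2, 8))
  rows <- list()
  if (L < 7) {
    return(data.frame(start = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  for (s in 1:(L - 5)) {
    if (substr(utr, s, s + 5) != m6) next
    m8 <- s >= 2 && substr(utr, s - 1, s + 5) == m7
    a1 <- s + 6 <= L && substr(utr, s + 6, s + 6) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
      if (a1) "7mer-A1" else "6mer"
    rows[[length(rows) + 1]] <- data.frame(
      start = if (m8) s - 1L else s, type = type,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# random DNA helper for test case generation
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
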