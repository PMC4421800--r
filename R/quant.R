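# Stage-wise expression, differential expression and biogenesis summaries.

#' Reads-per-million normalization
#'
#' Linear per-library scaling to one million reads: RPM = count * 1e6 /
#' library total. When all clean reads of a library are tabulated its RPM
#' column sums to exactly 1e6.
#'
#' @param counts numeric matrix (rows = tags/miRNAs, columns = libraries).
#' @param totals per-library clean-read totals (default: column sums).
#' @return RPM matrix of the same shape.
#' @export
rpm_normalize <- function(counts, totals = colSums(counts)) {
  if (any(totals <= 0)) stop("zero library total")
  sweep(as.matrix(counts), 2, totals, "/") * 1e6
}

#' Exact two-library differential expression test
#'
#' Compares one tag's counts between two libraries without replicates
#' using the exact conditional Poisson-rate test: under the null of equal
#' per-read rates, conditional on the row total `x + y` the count in
#' library A follows a binomial with probability `n_a / (n_a + n_b)`. The
#' two-sided p-value sums all outcomes no more probable than the
#' observed one (the standard exact-binomial definition), and is
#' symmetric under swapping the two libraries. Fold changes are computed
#' on RPM with a pseudocount; Benjamini-Hochberg adjustment is applied
#' across rows.
#'
#' @param counts_a,counts_b integer vectors of per-tag counts.
#' @param total_a,total_b library totals.
#' @param pseudocount RPM pseudocount for fold changes (default 0.01).
#' @param lfc_cut,padj_cut thresholds for the up/down flags (defaults
#'   |log2 FC| >= 1 and adjusted p < 0.05).
#' @return data.frame with `rpm_a`, `rpm_b`, `log2_fc`, `p`, `padj`,
#'   `direction` (`up`/`down`/`ns`, A relative to B).
#' @export
diff_expression <- function(counts_a, counts_b, total_a, total_b,
                            pseudocount = 0.01, lfc_cut = 1,
                            padj_cut = 0.05) {
  stopifnot(length(counts_a) == length(counts_b),
            total_a > 0, total_b > 0)
  rpm_a <- counts_a * 1e6 / total_a
  rpm_b <- counts_b * 1e6 / total_b
  log2_fc <- log2((rpm_a + pseudocount) / (rpm_b + pseudocount))
  p <- vapply(seq_along(counts_a), function(i) {
    ac_exact_p(counts_a[i], counts_b[i], total_a, total_b)
  }, numeric(1))
  padj <- p.adjust(p, method = "BH")
  direction <- ifelse(abs(log2_fc) >= lfc_cut & padj < padj_cut,
                      ifelse(log2_fc > 0, "up", "down"), "ns")
  data.frame(rpm_a = rpm_a, rpm_b = rpm_b, log2_fc = log2_fc, p = p,
             padj = padj, direction = direction, stringsAsFactors = FALSE)
}

# two-sided exact p: conditional on n = x + y, X ~ Binomial(n, pr) with
# pr = n_a / (n_a + n_b); p = sum of all outcome probabilities not
# exceeding the observed one (exact-binomial two-sided definition)
ac_exact_p <- function(x, y, n_a, n_b) {
  n <- x + y
  if (n == 0) return(1)
  pr <- n_a / (n_a + n_b)
  d <- stats::dbinom(0:n, n, pr)
  # tolerance guards against ties lost to floating-point noise
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

#' Stage-specificity class of an expression row
#'
#' Classifies a miRNA/tag by which stages exceed the presence threshold.
#'
#' @param rpm named numeric vector of per-stage RPM values.
#' @param threshold presence threshold (default 1 RPM).
#' @return character: `"not_expressed"`, `"<stage>"` for one stage,
#'   `"<stage a>+<stage b>"` for two, or `"three-stage"`.
#' @export
specificity_class <- function(rpm, threshold = 1) {
  stopifnot(threshold >= 0)
  on <- names(rpm)[rpm > threshold]
  if (length(on) == 0L) return("not_expressed")
  if (length(on) == length(rpm)) return("three-stage")
  paste(on, collapse = "+")
}

#' Specificity class table for an RPM matrix
#'
#' @param rpm_matrix matrix with stage columns.
#' @param threshold presence threshold.
#' @return data.frame with per-row `class` plus the class-count summary as
#'   attribute `summary`.
#' @export
specificity_table <- function(rpm_matrix, threshold = 1) {
  cls <- apply(rpm_matrix, 1, specificity_class, threshold = threshold)
  out <- data.frame(id = rownames(rpm_matrix), class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- table(cls)
  out
}

#' isomiR statistics per miRNA
#'
#' Groups tags onto known precursors as isomiRs of their parent mature
#' miRNA: a tag belongs to a parent when its templated portion matches the
#' precursor with a 5' offset within the window of the annotated mature
#' start, the 3' end within its window, and at most `max_nta`
#' non-templated 3' additions. The per-stage mean is the number of
#' distinct isomiRs observed in that stage divided by the number of
#' miRNAs observed in that stage.
#'
#' @param tags collapsed tag table with stage count columns.
#' @param precursor_refs named character vector of precursor sequences.
#' @param mature_annotation data.frame with `mature_id`, `precursor_id`,
#'   `mature_start`, `mature_end` (0-based half-open on the precursor).
#' @param stages stage column names.
#' @param window_5p,window_3p offset windows (defaults 2 and 4 nt).
#' @param max_nta maximum non-templated 3' additions (default 2).
#' @return list with `members` (data.frame tag_id, mature_id, off5, off3,
#'   nta, per-stage counts), `per_mirna` (isomiR counts), `mean_per_stage`
#'   (named numeric), and `unassigned` (count of tags matching no
#'   precursor).
#' @export
isomir_stats <- function(tags, precursor_refs, mature_annotation,
                         stages = STAGES, window_5p = 2L, window_3p = 4L,
                         max_nta = 2L) {
  members <- list()
  unassigned <- 0L
  for (i in seq_len(nrow(tags))) {
    seqv <- as_dna(tags$seq[i])
    hit <- NULL
    for (j in seq_len(nrow(mature_annotation))) {
      ma <- mature_annotation[j, ]
      prec <- as_dna(precursor_refs[[ma$precursor_id]])
      # try decreasing numbers of non-templated 3' bases
      for (nta_len in 0:min(max_nta, nchar(seqv) - 1L)) {
        core <- substr(seqv, 1L, nchar(seqv) - nta_len)
        pos <- as.integer(regexpr(core, prec, fixed = TRUE)) - 1L
        if (pos < 0L) next
        off5 <- pos - ma$mature_start
        off3 <- (pos + nchar(core)) - ma$mature_end
        if (abs(off5) > window_5p || abs(off3) > window_3p) next
        nta <- if (nta_len > 0)
          substr(seqv, nchar(seqv) - nta_len + 1L, nchar(seqv)) else ""
        # a "non-templated" base identical to the next precursor base is
        # templated; such tags were already caught at smaller nta_len
        hit <- list(mature_id = ma$mature_id, off5 = off5, off3 = off3,
                    nta = nta)
        break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) { unassigned <- unassigned + 1L; next }
    row <- data.frame(tag_id = tags$tag_id[i], mature_id = hit$mature_id,
                      off5 = hit$off5, off3 = hit$off3, nta = hit$nta,
                      stringsAsFactors = FALSE)
    for (s in stages) row[[s]] <- tags[[s]][i]
    members[[length(members) + 1L]] <- row
  }
  members <- if (length(members) > 0) do.call(rbind, members) else
    data.frame(tag_id = character(0), mature_id = character(0),
               off5 = integer(0), off3 = integer(0), nta = character(0),
               stringsAsFactors = FALSE)
  per_mirna <- if (nrow(members) > 0) table(members$mature_id) else
    table(character(0))
  mean_per_stage <- vapply(stages, function(s) {
    m <- members[members[[s]] > 0, , drop = FALSE]
    n_mirna <- length(unique(m$mature_id))
    if (n_mirna == 0L) return(0)
    nrow(m) / n_mirna
  }, numeric(1))
  list(members = members, per_mirna = per_mirna,
       mean_per_stage = mean_per_stage, unassigned = unassigned)
}

#' First-nucleotide bias by read length
#'
#' Frequency of each 5' base at each read length, computed on read counts
#' by default (or on unique tags).
#'
#' @param tags collapsed tag table.
#' @param stage stage column to weight by (NULL = total counts).
#' @param by_read weight by read counts (default) or count each unique
#'   tag once.
#' @return matrix (length x base ACGU), each row summing to 1; lengths
#'   with no reads are omitted.
#' @export
first_nt_bias <- function(tags, stage = NULL, by_read = TRUE) {
  w <- if (is.null(stage)) tags$total_count else tags[[stage]]
  if (!by_read) w <- as.integer(w > 0)
  keep <- w > 0
  first <- substr(tags$seq[keep], 1, 1)
  len <- tags$length[keep]
  w <- w[keep]
  lens <- sort(unique(len))
  m <- matrix(0, nrow = length(lens), ncol = 4,
              dimnames = list(lens, c("A", "C", "G", "U")))
  bases <- c(A = "A", C = "C", G = "G", U = "T")
  for (i in seq_along(lens)) {
    sel <- len == lens[i]
    tot <- sum(w[sel])
    for (b in names(bases)) {
      m[i, b] <- sum(w[sel & first == bases[[b]]]) / tot
    }
  }
  m
}

#' Arm usage labels for precursors
#'
#' For each precursor, sums read support on the 5p and 3p arms and labels
#' it `5p`, `3p` or `both`; the guide arm is the higher-count arm and the
#' star arm the lower (`co-dominant` on ties).
#'
#' @param arm_counts data.frame with `precursor_id`, `count_5p`,
#'   `count_3p`.
#' @return data.frame with added `label`, `guide`, `star`.
#' @export
arm_usage <- function(arm_counts) {
  lab <- with(arm_counts, ifelse(count_5p > 0 & count_3p > 0, "both",
                                 ifelse(count_5p > 0, "5p", "3p")))
  guide <- with(arm_counts, ifelse(count_5p == count_3p, "co-dominant",
                                   ifelse(count_5p > count_3p, "5p", "3p")))
  star <- ifelse(guide == "co-dominant", "co-dominant",
                 ifelse(guide == "5p", "3p", "5p"))
  cbind(arm_counts, label = lab, guide = guide, star = star,
        stringsAsFactors = FALSE)
}

#' Length distribution of reads per stage
#'
#' @param tags collapsed tag table.
#' @param stages stage columns.
#' @return matrix (length x stage) of read-count fractions per stage.
#' @export
length_distribution <- function(tags, stages = STAGES) {
  lens <- sort(unique(tags$length))
  m <- vapply(stages, function(s) {
    v <- tapply(tags[[s]], factor(tags$length, levels = lens), sum,
                default = 0)
    v / max(sum(v), 1)
  }, numeric(length(lens)))
  rownames(m) <- lens
  m
}

#' Hierarchical ordering of an expression matrix (convenience export)
#'
#' Plain average-linkage clustering on Euclidean distances of log2 RPM,
#' returning the row order; provided for heatmap-style reporting, not an
#' analysis surface.
#'
#' @param rpm_matrix RPM matrix.
#' @return integer row order.
#' @export
expression_ordering <- function(rpm_matrix) {
  if (nrow(rpm_matrix) < 3L) return(seq_len(nrow(rpm_matrix)))
  d <- stats::dist(log2(rpm_matrix + 1))
  stats::hclust(d, method = "average")$order
}
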