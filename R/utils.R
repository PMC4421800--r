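#' @useDynLib srnaflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom stats p.adjust pnbinom setNames runif
#' @importFrom utils write.table read.table
NULL

# Canonical internal alphabet is DNA: U is converted to T on input and back
# to U only where the field's convention prints RNA (consensus strings,
# precursor FASTA).

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and replaces U with T. The reverse (`dna2rna`) replaces T
#' with U.
#'
#' @param x character vector of sequences.
#' @return character vector in `A,C,G,T,N`.
#' @export
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of DNA strings
#'
#' @param x character vector (DNA alphabet, `N` allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    rc <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between equal-length strings; Inf if lengths differ.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Deterministic RNG scope: run `expr` under a seed without clobbering the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Random DNA string(s)
random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Plain TSV writers/readers used for every tabular external interface.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "")
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (DNA or RNA).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, DNA alphabet.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# GFF3 export of the internal feature table (1-based inclusive on disk).
# Internal coordinates are 0-based half-open; the +1 happens here only.
write_gff3 <- function(features, path, contig_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  gr$type <- features$class
  gr$ID <- features$feature_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(
    feature_id = as.character(gr$ID),
    class = as.character(gr$type),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
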