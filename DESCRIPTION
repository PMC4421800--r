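Package: srnaflow
Title: Small RNA Transcriptome Annotation, Novel miRNA Discovery and
    Evolution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for gonad small RNA sequencing analysis:
    adapter trimming and read collapsing, ungapped genome and ncRNA mapping,
    a fixed-priority annotation cascade (rRNA/tRNA/snRNA/snoRNA, repeats,
    exonic and intronic fragments, conserved miRNAs, piRNAs), novel miRNA
    discovery by hairpin folding under a nearest-neighbor energy model with
    explicit per-criterion rejection reasons, stage-wise expression and
    biogenesis statistics (RPM normalization, exact-test differential
    expression, isomiR and arm-usage accounting, first-nucleotide bias),
    miRNA family copy-number and genomic-cluster evolution analyses with
    neighbor-joining phylogenetics, and seed-match target-site scanning of
    3'UTRs. Includes a fully specified synthetic data generator that plants
    hairpins, piRNA clusters and decoy features with a complete truth table,
    so the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
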