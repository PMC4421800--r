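---
title: "Methods and design of the srnaflow pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the srnaflow pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

srnaflow reimplements, as tested and reusable code, the small-RNA
transcriptome workflow used to characterise gonad sex reversal: three
deep-sequenced libraries (ovary, ovotestis, testis) are cleaned,
collapsed, mapped, pushed through a hierarchical annotation cascade,
mined for novel miRNA hairpins, quantified stage by stage, and analysed
for miRNA family evolution and seed-match target sites. This vignette
explains the models and rules each stage implements, the parameters that
matter, what the synthetic data generator does and does not emulate, and
the design decisions that were genuinely open.

## The annotation model

A small-RNA library is modelled as a mixture of sequence classes:
degradation fragments of structural ncRNAs (rRNA, tRNA, snRNA, snoRNA),
fragments of exons and introns on either strand, repeat-derived
sequences, mature miRNAs (conserved or novel) with their isomiR
variants, piRNAs, and noise. Because one read can be compatible with
several classes, assignment is a fixed-priority cascade: each unique tag
receives the *first* class, in priority order, for which it has
evidence. Structural ncRNAs are removed first — their degradation
products would otherwise masquerade as small RNAs — then conserved
miRNAs, genomic-context classes, novel miRNAs and piRNAs; tags with no
evidence stay `unannotated`. The order is a configurable argument;
moving a class earlier can only grow its count (a property the test
suite checks), so the default order is a documented convention, not a
hidden assumption.

Evidence rules:

* genome mapping is ungapped with **0 mismatches**; ncRNA reference
  mapping allows **≤ 2 mismatches**; both report all hit loci on both
  strands.
* a conserved miRNA match needs **≥ 16 nt overlap** with a reference
  mature sequence, **no mismatch in the seed (positions 2–8 of the
  reference)**, **≤ 2 mismatches outside it**, and a **perfect match to
  the linked precursor**. The overlap floor absorbs imperfect Dicer
  processing at the read ends; the seed constraint reflects the seed's
  functional weight. Precursor matching is orientation-aware (a tag
  matching the precursor's reverse complement counts), because genome
  mapping is strand-symmetric and a hairpin's two strands are
  interchangeable genomic evidence.
* among isomiR variants sharing a mature locus the **highest-count tag**
  is the mature representative; ties break to the lexicographically
  smaller sequence so runs are reproducible.
* a piRNA is a tag of **24–32 nt** whose loci are intergenic (optionally
  also repeat-derived, controlled by `pirna_require_unannotated`) that
  reached the piRNA stage of the cascade. The 26–28 nt peak and the
  5′-uridine preference are *reported statistics*, never per-read
  filters: a piRNA population shows the bias; an individual piRNA need
  not.

## Novel miRNA discovery

Unannotated genome-mapped tags are grouped into piles of overlapping
loci. Each pile's modal 5′ end defines the *cutting site*; its summed
read count is the cutting-site depth, our operationalisation of "depth
of the Drosha/Dicer cutting site" (configurable; the modal-terminus
definition rewards the precise 5′ ends real Dicer products have). The
±100 nt window around the representative tag is folded; the mature arm
is the tag, the star arm is inferred from the pairing partners of the
mature arm with the canonical 2 nt 3′ overhang; the precursor is trimmed
to the arms plus a 10 nt flank and re-folded.

A candidate is accepted iff **all** criteria hold (defaults in
`discovery_params()`):

| criterion | default | unit |
|---|---|---|
| mature length | 18–26 | nt |
| cutting-site depth | ≥ 3 | reads |
| genomic copies of the mature tag | ≤ 20 | loci |
| precursor free energy | ≤ −18 | kcal/mol |
| space between mature and star arms | ≤ 35 | nt |
| mature/star duplex pairs | ≥ 14 | base pairs |
| longest bulge inside the duplex | ≤ 4 | nt |
| duplex asymmetry | ≤ 5 | nt |

Rejections list *every* violated criterion by name, so a rejected locus
is diagnosable. Cheap criteria (length, copies, depth) are checked
before folding. Candidates whose precursor intervals overlap are
deduplicated (accepted beats rejected, then deeper); this also merges
the mirror-image candidate that every hairpin produces on the opposite
strand. Relaxing any single threshold can only grow the accepted set —
a monotonicity property the acceptance tests verify threshold by
threshold.

Bulge and asymmetry are defined operationally: within the duplex span
(first to last inter-arm pair on each arm), `bulge` is the longest run
of consecutive unpaired bases on either arm and `asymmetry` the absolute
difference of the two arms' unpaired counts. The original prediction
software's internal definitions are not published; ours are stated,
implemented, and tested against an independent structure-walk oracle
rather than against that tool.

## The folding engine

Precursor candidates are single stem-loops, so the energy model is
restricted to *hairpin-class* structures: one nested chain of canonical
pairs (Watson–Crick + GU), i.e. a single helix interrupted by bulges and
internal loops, closed by a terminal loop — no multiloops, no
pseudoknots. The model is nearest-neighbor: a 6×6 stacking table over
pair types (Turner-style magnitudes), logarithmic loop penalties
(hairpin `5.4 + 1.08·log(n/3)` for n ≥ 3 unpaired; bulge
`3.8 + 1.08·log n`; internal loop `4.0 + 1.08·log((a+b)/2)` plus a
capped asymmetry term), no dangles or special tetraloops. The minimum
free energy is computed by an interval dynamic program in C++
(O(n²·L²) with loop sides capped at L = 30 nt), with penalties
precomputed in R so the C++ and R routes are bit-identical. The empty
structure has energy 0 and the reported ΔG is never positive.

This self-contained model keeps an exhaustive enumeration oracle exact:
for sequences ≤ 18 nt the test suite enumerates *every* admissible chain,
scores each with the standalone `structure_energy()`, and requires the
dynamic program to match over 200 random sequences. An external folding
backend can be substituted behind the same `fold()` contract; the test
and acceptance surfaces use the internal model.

## Quantification choices

* **RPM**: counts are scaled to one million reads per library
  (`count × 10⁶ / clean-read total`); when all clean reads are
  tabulated each column sums to exactly 10⁶, a conservation law checked
  on every synthetic run.
* **Differential expression** between two libraries without replicates
  uses the exact conditional Poisson-rate test: given the row total
  `x + y`, the count in library A is Binomial(`x + y`,
  `n_a / (n_a + n_b)`) under the null of equal per-read rates; the
  two-sided p sums all outcomes no more probable than the observed one.
  This conditioning is symmetric — swapping the libraries inverts the
  fold change and leaves p identical — which the one-sided
  posterior-predictive variant of the classic two-library test is not.
  p-values are BH-adjusted across rows; rows are flagged up/down at
  |log2 FC| ≥ 1 and adjusted p < 0.05 (the fold-change-of-two
  convention; a p cutoff had to be fixed here and 0.05 is the field
  default). Fold changes use a 0.01 RPM pseudocount so stage-specific
  miRNAs have finite fold changes.
* **isomiRs**: a tag joins a miRNA's isomiR set when its templated
  portion matches the precursor with a 5′ offset within ±2 nt of the
  annotated mature start, a 3′ offset within ±4 nt, and ≤ 2
  non-templated 3′ additions — windows chosen to cover RNase-III
  cleavage wobble and tailing while excluding unrelated fragments. A
  "non-templated" base identical to the next precursor base is
  templated and recorded as a 3′ offset instead. Tags failing the
  cascade's perfect-precursor rule (true non-templated tails) are still
  collected here: isomiR membership is a sequence-evidence question,
  not an annotation-category one.
* **Arm usage**: the guide arm is the higher-count arm, the star the
  lower, `co-dominant` on ties; a precursor with reads on both arms is
  labelled `both`. Tags are assigned to arms by their substring position
  on the oriented precursor, which avoids double-counting the mirrored
  minus-strand genome hit every hairpin tag has.

## Evolution and targets

Family grouping is name-based (`miR-n-1…-n-n`, `miR-na…-nz`; species
prefixes ignored), which matches how miRNA homolog groups are curated;
no sequence-based orthology is attempted. Clusters are single-linkage
chains of precursors within `max_gap` (default 10 kb — observed cluster
spans are hundreds of bp, and the chaining window just needs to sit well
above span scale and below inter-cluster distances; it is configurable).
Consensus sequences use the modal base per column, uppercase iff its
frequency reaches 0.9 (reproducing the conventional mixed-case display
of family consensus sequences), ties broken in fixed base order.
Distances are p-distances with pairwise deletion; trees are standard
neighbor-joining (exact on additive matrices — verified on 100 random
trees of 4–10 taxa), and bootstrap support resamples alignment columns
with a fixed seed. Multiple sequence alignment itself is out of scope:
the module consumes pre-aligned FASTA.

Target sites are typed purely by seed match — 8mer, 7mer-m8
(positions 2–8), 7mer-A1 (positions 2–7 plus an A opposite position 1),
6mer — each UTR window reported once with its most stringent type.
Positions are counted 1-based from the miRNA 5′ end; the "A" of
A1-types is an adenosine in the UTR regardless of complementarity. No
context or free-energy scoring is applied: site typing is the analysis,
repression prediction is not.

## The synthetic data generator

`build_toy_genome()` plants every feature class the cascade knows about
on one contig with 200 nt spacing (so genic/intergenic labels are
unambiguous): conserved hairpins whose matures double as the
miRBase-style reference set (both arms, as `-star` entries), novel
hairpins constructed as perfect 22 bp stems and *verified against the
discovery checker during generation*, decoy hairpins each engineered to
violate exactly one criterion (AT-only stems for the energy decoy,
13-pair GC stems for the pair-count decoy, oversized loops, engineered
bulges and asymmetric insertions, 27 nt matures, read-starved and
21-copy variants), intergenic piRNA clusters, structural ncRNAs, gene
models with exons/introns/3′UTRs, and two-copy repeats. Decoy stems use
alphabet-restricted flanks (inert bases that cannot pair with the stem)
so their designed metrics survive folding in genomic context.

`simulate_libraries()` emits 50 nt raw reads — insert + 3′ adapter +
filler, as a sequencer would deliver them — with a complete truth table.
Conserved-miRNA reads carry isomiR jitter (5′ ±1, 3′ ±2, 5%
non-templated additions); piRNA reads sample lengths peaking at
26–28 nt and enforce the 5′-U probability (default 0.8) *by start-site
choice* — a U-start position is selected with exactly that probability —
so reads stay perfectly genome-mappable and the realised frequency is
unbiased. Stage structure follows the study design: conserved miRNAs
expressed in all three gonad stages, novel miRNAs mostly stage-specific,
piRNA pools testis-enriched, 2% uniform-random noise reads.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: sequencing errors and quality-score
structure (qualities are constant), ping-pong piRNA biogenesis
signatures, expression dispersion across biological replicates, multi-
contig genomes with assembly artefacts, and miRBase-scale reference
heterogeneity. Tests against the truth table demonstrate that the
*rules are implemented correctly*, not that the rules are optimal for
any particular organism.

## Numerical and reproducibility notes

* Coordinates are 0-based half-open internally; GFF3 and printed site
  spans convert to 1-based inclusive at I/O boundaries only. U and T are
  interchangeable on input; the internal alphabet is DNA.
* All randomness flows from explicit seeds (`genome_spec(rng_seed)`,
  `pipeline_config(seed)`); the same config reproduces every output
  byte for byte, which the test suite asserts by hashing all written
  files across two runs.
* Ties are broken deterministically everywhere (lexicographic sequences
  for mature representatives, fixed base order in consensus, stable
  ordering in candidate deduplication).
* Degenerate inputs are defined, not accidental: empty structures fold
  to ΔG 0; all-zero expression rows class as `not_expressed`; tags
  matching nothing are `unannotated`, never an error; zero library
  totals and zero-comparable-site pairs raise named errors.
* Default test and acceptance problem sizes: a ~31 kb toy genome, 20
  planted novel hairpins, 10 decoys, 3 piRNA clusters and ~15,000 reads
  across the three stages; folding-oracle sweeps use 200 sequences of
  8–18 nt; the mapper oracle runs on a 50 kb two-contig reference; NJ
  consistency uses 100 random trees of 4–10 taxa. These sizes exercise
  every rule at full stringency while keeping a complete run in the
  minutes range on one CPU.

## Known limitations

* The cascade assigns one category per tag; multi-locus tags with
  conflicting contexts resolve by priority, not probabilistically.
* Cutting-site depth uses total counts across stages; a hairpin
  supported only by diffuse 5′ ends is rejected even at high coverage,
  by design.
* The folding model's hairpin-class restriction is right for precursor
  screening but unsuitable for general RNA structure prediction.
* Family grouping trusts nomenclature; mis-named references yield
  mis-grouped families (unparseable names pass through with a warning).
* piRNA calling is positional and length-based; no ping-pong signature
  or transposon-family attribution is attempted.
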