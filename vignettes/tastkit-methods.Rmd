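---
title: "Methods and design notes for tastkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for tastkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tastkit)
```

tastkit is a toolkit for studying a gene locus with two complementary data
types: a high-accuracy genomic contig (for example a ~100 kb BAC clone) and
full-length transcripts from long-read RNA sequencing. It was designed around
a hard instance of that problem — a metallothionein gene whose first two
exons are only ~22 and ~26 bp long, whose first intron carries a 10–19 kb
tandem-repeat array of ~180 bp monomers, and whose transcript family is best
recognised not by length but by cysteine content. All analyses consume and
produce tibbles, so each step composes with ordinary dplyr pipelines, and
each fitted result type has `tidy()`/`glance()` and `autoplot()` methods.

This vignette explains the models and procedures, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the design choices made where the problem was genuinely open. It states
no empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## Transcript-to-locus alignment structures

The input is a set of local alignments (HSPs) of transcripts against one
genomic target, read from standard 12-column BLAST tabular output with
`read_blast_tab()`. Internally every coordinate is 0-based half-open;
1-based inclusive coordinates exist only at the BLAST-tab boundary. Only the
exact 12-column dialect is accepted, and malformed lines are reported with
their line number: the parser is a contract, not a guess.

`chain_transcript_alignments()` turns the HSPs of each transcript into an
ordered exon-block structure:

1. Blocks are sorted along the transcript and numbered from zero.
2. Among all subsets of blocks in which every pair of consecutive retained
   blocks lies within `max_intron` bp on the genome, the subset with maximal
   summed bitscore is selected (an exact O(n²) chaining DP). This is the
   deterministic version of "split at overlong introns and keep the better
   side": the test suite checks it against brute-force enumeration of all
   subsets on small instances.
3. Transcripts whose surviving blocks cover less than `min_coverage` of
   their length (union of query intervals) are dropped.

**Junction overlap trimming.** A local aligner extends each exon alignment
independently, so whenever the intron sequence happens to continue like the
next exon, two consecutive blocks double-align the same transcript bases.
With `trim_query_overlaps = TRUE` (default) the overlap is trimmed from the
block with lower percent identity (ties: the upstream block), moving its
genomic edge by the same amount; the trim assumes the alignment is ungapped
near the junction, which holds for short overlaps. After trimming each
transcript base is reported aligned at most once, which is what downstream
exon inference wants. Disable it to see raw HSP extents.

`detect_collinearity()` walks the blocks in genomic order and groups maximal
runs whose transcript order indices are non-decreasing in steps of 0 or +1
(e.g. 1, 2, 3, 3). Such runs are the visually meaningful "this region of the
genome reads like the transcript" signal and are shaded in the plot. A
single block is trivially collinear, so the runs always partition the
blocks.

ORF annotation uses `find_orfs()`: standard codon table, ATG start, TAA/
TAG/TGA stop; one ORF per (frame, stop codon) anchored at the 5'-most ATG of
its unit, the stop codon inside the `[start, end)` interval but excluded
from the protein. `require_stop = FALSE` admits open-ended ORFs for
truncated reads. The longest ORF (ties broken 5'-most, for determinism) is
the reference for block colouring: blocks overlapping it by at least 1 bp
are class `longest_orf`, blocks overlapping any other ORF `minor_orf`, the
rest `non_orf`. One shared base is the simplest testable overlap rule.

`splice_boundary_error()` scores exon placement: for every internal block
edge (all genomic starts/ends except the outermost two) it takes the
distance to the nearest annotated exon boundary and sums them. Whether such
a figure should be per junction or summed is a convention; the summed form
is reported together with the internal edge count, so either normalisation
can be formed.

**Splice ambiguity and what a green test establishes.** When an intron
begins with the same bases as its downstream exon (or ends with the same
bases as its upstream exon), several donor/acceptor placements splice to the
*identical* transcript. No aligner without splice-site information can
prefer one — and splice-consensus scoring is deliberately outside the
chaining model here. The locus simulator therefore reports as truth
`boundaries` every equivalent placement (`equivalent_splice_boundaries()`),
keeping the strict construction edges in `exon_boundaries`. A perfect score
against the equivalence set means "the placement is within the ambiguity
run", not "the aligner guessed the generator's arbitrary choice".

## Repeat architecture

`self_alignment_depth()` counts, at every coordinate, how many self-
alignment HSPs cover it. The full-length identity diagonal is excluded and
exact (q,s)/(s,q) mirror pairs are counted once; each remaining HSP
contributes +1 over its query interval and +1 over its subject interval.
Whether a published depth curve counts query intervals, subject intervals or
both is rarely stated; counting both is the symmetric choice — the profile
is then invariant under swapping query and subject, which is also the
invariant the tests assert.

`split_monomers_at_troughs()` automates cutting a tandem array into
monomers at the troughs of the depth profile (a task often done manually):
the profile is smoothed by a centred moving average (`smoothing_window`,
default 25 bp), local minima are found (a flat minimal plateau is cut at its
centre), and only *troughs* — minima below `trough_frac` (default 0.5) of
the region's median smoothed depth — become cuts. The threshold rejects the
shallow dips that chance sub-repeats inside monomers produce. Explicit
breakpoints bypass detection so that manual splits can be reproduced.

Monomers are then characterised by their decamer composition
(`kmer_feature_matrix()`, overlapping counts, k = 10), reduced to two
principal components, and clustered with DBSCAN (`cluster_monomers()`).
Numerical choices:

* Counts are mean-centred but not scaled to unit variance: k-mer counts
  share a unit, and unit-variance scaling would inflate rare k-mers.
* A zero-variance feature matrix (all monomers identical) reports
  `variance_captured = 1` by convention.
* No DBSCAN implementation ships in the installed stack, so the classic
  algorithm is implemented here (Euclidean, labels −1 for noise).
* `eps` default: the smallest radius at which **every** monomer is a core
  point (the maximum k-distance at `k = min_samples`). At that radius the
  clusters are the connected components at the coarsest all-core scale. The
  textbook sorted-k-distance-knee heuristic is available as `eps = "knee"`,
  but for well-separated repeat families with small `min_samples` it
  systematically picks a radius far below the within-family connectivity
  scale and shatters clusters — on the two-template fixture the knee sits
  near 0.6–0.8 where any radius between the within-family maximum
  (~3) and the between-family gap (~12) is correct. Both are overridable.

`monomer_stats()` reports min/max/mean length and mean GC, with the rounded
forms produced by half-away-from-zero rounding.

## Pairwise identity between two long sequences

Given all local alignments between two sequences, `best_identity_track()`
records at each coordinate the highest percent identity among the
alignments covering it (stored as a fraction; percent appears only in
figures). `total_identity()` then forms

> T = I / L,

where I is the sum of the per-coordinate best identities over both
sequences and L the sum of the two lengths. T is 1 exactly when both
sequences are fully covered by 100%-identity alignments. Reverse-strand
alignments contribute by their coordinate span — the statistic is
orientation-agnostic. Two caveats are intrinsic and are demonstrated
constructively in the tests: repeats present in unequal copy number inflate
T (one copy aligns to many places on the partner), and rearrangements are
invisible to it (order is never examined). The comparison figure
(`autoplot()` on the result, with the HSP set) therefore draws the
per-alignment connectors, whose thickness and opacity encode bitscore
normalised to the maximum of the plotted set and whose colour encodes
strand, precisely so that multiplicity and rearrangement stay visible.

## Long-read preprocessing

`filter_by_quality()` interprets a "Q30 filter" as mean Phred ≥ 30
(boundary inclusive); read-level predicted accuracy is an equivalent
formulation at the default.

`demultiplex_barcodes()` searches every barcode and its reverse complement
within the first and last `window` bp (default 150) of each read by
Hamming-distance scanning with `max_mismatches` (default 2). Exact scanning
is deterministic and dependency-free; a BLAST-based search is an equally
valid backend for the same contract. A read is `assigned` only when both
ends match the same barcode; reads matching at one end only are discarded
(status `one_end_only`), and reads whose two ends match different barcodes
are discarded as likely chimeras (`conflicting_ends`).

`orient_by_polya()` orients reads by the poly-A tail: a terminal A-run of at
least `min_tail` bp (default 10) inside the last `search_window` bp (default
50) keeps the read forward, a corresponding leading T-run reverse-
complements it, ties and absence filter the read. The thresholds are
configuration, not biology: they were chosen once as values a PacBio
full-length pipeline would consider unremarkable.

`preprocess_reads()` chains the three steps, demultiplexing before poly-A
orientation (the order is otherwise arbitrary). Because the barcode
geometry `barcode … revcomp(barcode)` reads the same on both strands,
orientation must come from the poly-A signal; assigned reads that fail it
get the distinct status `no_polya`, so `assigned` always implies an
oriented read. `compute_n50()` is the usual largest L such that sequences
≥ L hold at least half of the total.

## Transcript-family mining

The mining model is built around cysteine-rich proteins (metallothioneins):

* `mine_transcripts_by_exon()` keeps transcripts hit by an exon query at or
  above a bitscore threshold.
* `select_cysteine_rich_orf()` scans **all** ORFs of a transcript, including
  alternative in-frame ATGs inside each (frame, stop) unit, and returns the
  one with most cysteines (ties: longest, then 5'-most). The longest ORF is
  often not the coding one in this family; cysteine count is the better
  recogniser. Candidates below `min_cys` (default 10) are rejected.
* `dedupe_protein_clusters()` removes redundancy at 100% protein identity,
  keeping member ids and counts.
* `classify_by_utr()` assigns each transcript the clade of its top-scoring
  3'-UTR query above a threshold; an exact top-score tie between clades is
  reported `unclassified` rather than resolved arbitrarily.
* `tissue_summary()` computes each tissue's share of all transcripts and of
  target-family transcripts and their ratio (the representation ratio,
  > 1 = enrichment). All derived columns are computed from unrounded
  fractions and then rounded half-away-from-zero to one decimal; the ratio
  formula was inferred from the published table it reproduces cell-for-cell
  in the acceptance tests.
* `splice_site_consensus()` builds, per column of fixed-width junction
  flanks, the minimal IUPAC code covering every base at frequency ≥
  `ambiguity_threshold` (default 0.25; below it, observed bases are all
  covered, possibly giving N), plus the mean pairwise positionwise percent
  identity — "average % identity" is taken as pairwise, the only
  self-contained reading.
* `scan_motif()` matches IUPAC patterns (e.g. the AATAAA poly-A signal)
  under subset semantics: a concrete sequence base must belong to the
  pattern character's set. No metal-responsive-element default pattern is
  shipped, because no authoritative definition is bundled with the package;
  the pattern is always user-supplied.

## The synthetic world

`simulate_locus()` generates the stated test world: exon lengths default to
22, 26, 150, 250 bp (the short-exon regime the toolkit exists for), introns
default to 1500, 400, 400 bp — deliberately desk-scale rather than the
10–19 kb of the motivating locus, so suites stay inside their time budgets —
flanks of 400 bp, background GC 0.42 (the observed GC of the motivating
repeat monomers), canonical GT…AG intron ends, and a planted ORF between a
30 bp 5' UTR and a 100 bp 3' UTR with premature in-frame stops recoded.
An optional tandem-repeat array is inserted mid-intron-1 with per-copy
truth labels.

`simulate_monomer_array()` mutates template copies at `sub_rate` and
additionally hyper-mutates the outer `junction_width` bp of each copy
(default 10 per side at rate 0.6). This junction decay emulates the fact
that real satellite junctions are where divergence, truncation and indels
accumulate — and it is load-bearing: identical abutting copies self-align
at *constant* depth, so an array without junction divergence has no troughs
and the trough-splitting operation would have nothing to detect. The decay
width must exceed roughly half the smoothing window to survive smoothing,
which fixes its order of magnitude. For clustering experiments the decay
can be switched off (`junction_width = 0`) to obtain the pure
"templates + uniform substitution" world.

`simulate_reads()` builds each read as
`barcode + transcript + polyA + revcomp(barcode)`, flips it with
probability 0.5, applies i.i.d. substitutions, and assigns flat Phred
scores consistent with the substitution rate. Not emulated: homopolymer
indels, chimeras, quality-score calibration, length-dependent error — a
green preprocessing test establishes correct bookkeeping and mismatch
tolerance, not performance on real PacBio error profiles.

`naive_local_align()` is the BLAST stand-in that keeps the whole toolkit
testable offline: exact `word_size` seeds (default 4), ungapped ±extension
with +1/−2 scoring and X-drop 6, per-diagonal merging, both strands. Its
`bitscore` is the raw score and its `e_value` a placeholder 0, so fixture
filtering is always done on bitscore or identity. It is validated against
Smith–Waterman local alignment (Biostrings) on small instances, and it is
*not* a BLAST reimplementation: gapped alignment, statistics and scaling are
out of scope.

All generators are pure functions of their arguments and a seed (the global
RNG state is saved and restored).

## Command line

The installed script `inst/scripts/tastkit` dispatches to `tast_cli()`,
which validates parameters (precedence: flags > JSON config file >
defaults) and writes the effective configuration as a JSON artifact next to
the outputs, so any run can be reproduced from its own record. The
subcommands map one-to-one onto the functions above.

## Known limitations

* The chainer keeps transcripts whose blocks align to both target strands;
  strand is rendered per block. Genuinely trans-spliced or inverted
  transcripts deserve better treatment.
* Junction trimming uses whole-block percent identity as a proxy for the
  identity of the overlapping segment (HSP tables carry no per-base
  alignment), and assumes the alignment is locally ungapped.
* T = I/L loses local resolution by design; see the caveats above.
* DBSCAN parameters remain data-dependent; the all-core default is robust
  for well-separated families but a continuum of repeat variants will still
  require a manual `eps`.
* The fixture aligner's ungapped model understates errors for indel-rich
  reads; conclusions about indel robustness cannot be drawn from it.
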