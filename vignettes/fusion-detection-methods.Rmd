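---
title: "Detecting fusion genes with fusionlite: model, filters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fusion genes with fusionlite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionlite)
```

## The detection problem

A fusion gene joins parts of two distinct genes through a chromosomal
rearrangement; when expressed it produces a chimeric transcript whose 5'
portion comes from one gene and whose 3' portion comes from another.
In paired-end RNA-seq such transcripts leave two kinds of evidence:

* **spanning pairs** ("mapped reads"): the two mates map, individually
  and near-fully, to transcripts of two *different* genes, so the
  unsequenced fragment interior must straddle the junction;
* **split reads**: a single mate maps partially to both genes, with the
  switch point pinpointing the junction at base resolution.

`fusionlite` detects both signals from a lightweight k-mer quasi-mapping
of the read pairs against the annotated transcriptome — no base-level
alignment, no genome mapping — and then applies a cascade of statistical
screens to remove the artifacts that dominate naive discordant-read
calling.

## Quasi-mapping model

The transcriptome is held in a hash index of all canonical k-mers with
their (transcript, offset, orientation) occurrences (`build_index()`).
A read is mapped greedily (`map_read()`): from the leftmost query
position carrying an indexed k-mer the match is extended base-by-base
along every hit transcript while bases agree; the segment keeps the
transcripts supporting the maximal extension, and the scan resumes after
the segment. Both read orientations are attempted and the one covering
more bases wins (ties go forward). This is a deliberately simple
maximal-mappable-extension scheme: downstream logic depends only on the
segment structure (which transcripts, which offsets, how many matched
bases), not on any particular aligner's internals. Hyper-repetitive
k-mers (more than `max_postings` = 200 occurrences) are skipped and act
as mismatches, the standard pseudo-alignment guard against low-complexity
regions.

Two parameters matter:

* `k` (k-mer length, bases): 21 for reads shorter than 70 bp, else 31
  (`choose_k()`). Split-read detection needs `k < r/2`, since a chimeric
  read must carry a full k-mer on each side of the junction.
* `r` (read length, bases): enters only through the near-full-mapping
  threshold `r - k - 1`, which tolerates one disrupted k-mer plus one
  base at a read end without scored alignment.

For a pair, `T1`/`T2` are the transcripts to which mate 1/2 maps with at
least `r - k - 1` matched bases. `S = T1 ∩ T2` is the concordant set;
`S1 = T1 − S` and `S2 = T2 − S` the discordant sets. A pair with
non-empty `S` is ordinary (concordant); a pair with empty `S` but both
sides near-fully mapped to different genes is a spanning pair; a pair
with one chimeric mate (two segments of at least `k` bases from disjoint
gene sets) whose partner anchors in one of the two genes is a split
read.

## Fusion equivalence classes

Spanning pairs are counted through *fusion equivalence classes*. Each
discordant pair generates the ordered candidate set `S1 × S2` of
(5' transcript, 3' transcript) combinations (`fusion_transcripts()`);
pairs generating exactly the same candidate set are grouped into one
class with fragment count `c_j` (`build_feq_table()`). Fragments whose
candidate set involves two transcripts of the same gene are discarded
outright — they are indistinguishable from ordinary isoform ambiguity.
For a fusion gene (gene pair) the raw support is the sum of `c_j` over
classes containing any of its candidate transcripts (`support_count()`),
and the corrected count down-weights ambiguous classes by
`w_j = 1 / (number of candidate transcripts in the class)`
(`corrected_count()`), each class contributing once per gene pair. The
corrected count can never exceed the raw count; the two coincide exactly
when every class supporting the pair is unambiguous.

One ambiguity in this accounting is deliberate: when a class contains
several candidate transcripts of the *same* gene pair the class weight
is applied once, not once per member transcript — the weight corrects
for reads shared *between* gene pairs, and a gene pair should not be
rewarded for having many isoforms. The alternative (per-transcript
contribution) is a one-line change in `corrected_count()`.

### 5'/3' direction

For an unstranded library a spanning pair alone cannot reveal which gene
is 5': sequencing either strand of the fragment produces one
forward-mapping and one reverse-mapping mate. Split reads *do* carry the
direction (segment order along the mapped orientation), so the pipeline
calls split-read junctions first and folds spanning evidence onto the
split-read-established direction for that gene pair. Without any split
evidence, mate 1 is taken as the 5' side; the evidence then splits
between the two directions and the inverted-fusion filter keeps the
better-supported one. This loses at most half the spanning support for
split-free candidates, which is the honest price of an unstranded
library.

## Split-read junctions

For each split read the first and last matched segments give the 5' and
3' transcript coordinates of the junction. Junction micro-homology —
bases immediately after the breakpoint that are identical in both
constituent transcripts — makes several (5', 3') representations of one
junction sequence-equivalent; `fusionlite` reports the *maximal-5'*
form (homology assigned to the 5' side) everywhere, including the
simulator's truth tables, so called and implanted coordinates are
directly comparable. Within a gene pair the breakpoint is the modal
genomic junction over supporting reads, ties broken by the number of
reads anchored in the 5' gene, then by the smaller coordinate
(`call_junctions()`).

Two per-read screens precede junction calling:

* **misalignment screen** (`misalignment_screen()`): a "split" read
  whose sequence extends contiguously along a *single* constituent
  transcript over more than 85% of its length is better explained by
  one gene and is dropped (strict `>`; the 85% threshold follows the
  method this package implements);
* **overlap screen** (`overlap_screen()`): if the two sides' maximal
  extensions overlap on the query by more than `max_overlap` (default
  10) bases, the "junction" lies in a long region shared by both genes
  — paralog-like similarity, dropped. The default is a package choice;
  the screen's purpose is qualitative (a true junction has at most a
  few bases of micro-homology).

If a genome FASTA is supplied, the dinucleotides flanking the breakpoint
are classified against the canonical splice motifs (GT-AG, GC-AG,
AT-AC), strand-aware. The motif is annotative only — candidates are
flagged, never removed, because genuine fusion junctions need not reuse
canonical splice sites.

## The filter cascade

Filters run in a fixed order: general features → positional
(duplicates, fragment lengths, junction distance) → sequence similarity
→ inverted fusions → annotative flags. Drop decisions that do not
modify counts are order-insensitive; the order matters only for the
count-modifying steps (deduplication before support thresholds).

**General features** (`general_filter()`): candidates must live on
ordinary chromosomes (1–22, X, Y), involve two protein-coding genes, and
keep a minimum genomic separation when the genes share a chromosome
(default 100 kb — read-through transcription between neighbouring genes
is the dominant artifact there; different chromosomes always pass).
Spanning support must reach `min_mr_support` (default 2) and split
support `min_sr_support` (default 1).

**Positional distribution** (`positional_filter()`): supporting pairs
with identical (5' start, 3' start) positions collapse to one —
PCR/optical duplicates inflate support but carry one fragment of
information. Implied fragment lengths (5' start to breakpoint plus
breakpoint to 3' end) are screened by a robust z-score,
`|x − median| / (1.4826 · MAD)`, dropping pairs beyond `fraglen_z_max`
(default 5): a read pair whose implied fragment is wildly long for the
library is a mismapping, not evidence. When the MAD is zero the median
is taken as exact — identical lengths all pass, while any value off the
median is treated as infinitely deviant (this keeps the screen
meaningful for heavily duplicated support where more than half the
lengths coincide). Finally, same-chromosome breakpoints closer than
`min_junction_distance` are dropped as likely splice artifacts.

**Sequence similarity** (`build_similarity_reference()`,
`similarity_filter()`): genes with near-identical stretches produce
systematic discordant pairs. Besides optional curated paralog and
read-through lists, the package derives a similarity reference from the
data itself: it simulates an error-free sample in which every transcript
receives the same read count (default 1000, seeded), maps it back, and
records every gene pair whose transcripts co-occur in a concordant hit
set — genes confusable by the mapper necessarily co-occur because every
transcript is expressed. Candidates on any referenced pair are dropped.
A shared-support screen additionally removes spanning candidates whose
fragments are more than 50% shared with a better-supported candidate
(redundant explanations of the same reads).

**Inverted fusions** (`inverted_fusion_filter()`): expression of both
(A,B) and (B,A) would imply a circular arrangement; the lower-scoring
direction is dropped, and an exact tie drops both.

**Annotative tests** (flag, never drop): a two-sided binomial test
compares the observed split fraction among junction-covering reads with
an expected `p0` (default 0.5) and flags strong inconsistency at
p < 0.01 — single-evidence candidates are legitimate (a short fragment
library may produce no split reads at all), so this cannot be a hard
filter. Gene-set flags (mitochondrial translation, ribosomal subunits,
ribonucleoproteins) are reported for the user's judgement.

## Scoring

The score of a candidate is the corrected spanning count plus the
corrected split count; split reads enter with weight 1 each (a split
read pinpoints a unique junction, so the equivalence-class multiplicity
correction has no analogue on that side). Candidates below score 3
are removed — applied after the inverted-fusion filter, so a direction
decision cannot be rescued by the discarded direction's evidence — and
the rest are ranked by score, ties broken by split support, then gene
ids, for deterministic output.

## The simulator, and what passing tests do and do not show

`simulate_transcriptome()` generates i.i.d. random exon sequences (at
k ≥ 21, cross-gene k-mer collisions are vanishingly rare), 2–4 exons
per gene, two isoforms per gene by exon dropping (so intra-gene
ambiguity is realistic), genes laid out over chromosomes 1–22 with at
least 1 Mb spacing. `implant_fusions()` joins transcript prefixes to
suffixes with breakpoints uniform in the middle 60% of each transcript,
partner genes always on different chromosomes, truth stored in the
maximal-5' form. `simulate_reads()` draws fragments with
Normal(250, 25) lengths truncated to `[r, L]` (defaults; both
configurable), error-free bases, unstranded by default (each fragment
flips strand with probability 1/2), optional exact-duplicate fraction
for the deduplication screens, and junction-covering placement for
fusion fragments so that "abundance = 100" means one hundred
informative fragments.

Defaults used in the validation runs are the package's study
conditions: 50 genes × 2 isoforms, 5 inter-chromosomal fusions at 100
junction-covering fragments each, 50,000 background fragments, 100 bp
reads, k = 31. These sizes keep a full run (including the
1000-reads-per-transcript similarity simulation) under a minute on one
CPU.

Passing on such data shows the *accounting* is right: classification
thresholds, equivalence-class counting, breakpoint arithmetic, filter
logic, determinism. It deliberately does not exercise sequencing
errors, indels, intron retention, polymorphism against the reference,
expression covariance, or genuine paralog families — real-data behavior
depends on screens (similarity reference, robust fragment-length test)
whose thresholds are only meaningfully stressed by real libraries. The
error-free choice is principled: every classification rule in the
method is a threshold on matched bases, so an error model would blur
unit boundaries without changing any decision logic.

Pairs whose junction falls within `k` bases of a mate's end are
legitimately unrecoverable (the minority side carries no complete
k-mer) and may classify as concordant; the per-class tests assert
recovery only for geometries the definitions can see.

## Numerical and degenerate-input choices

* Coordinates: GTF stays 1-based inclusive at the boundary; mapping
  internals are 0-based half-open (C++); all R-facing structures are
  1-based with inclusive ends.
* Transcript version suffixes (".N") are stripped when matching FASTA
  to GTF identifiers, the usual Ensembl convention.
* Non-protein-coding transcripts are indexed for mapping (their reads
  must land somewhere or they would contaminate fusion evidence); the
  biotype filter acts at candidate level.
* Empty inputs degrade explicitly: an empty candidate list exports a
  header-only TSV; an all-zero contingency table returns p = 1; zero
  validated fusions yield `NA` metrics rather than silent zeros.
* The Fisher precision comparison between two callers contrasts each
  caller's true-positive count against its total discovery count in a
  2×2 exact test, two-sided by the standard
  sum-of-smaller-probabilities convention (`stats::fisher.test`); the
  published comparisons this package reproduces are computed under
  exactly that table layout.
* Benchmark tables print two decimals with half-away-from-zero
  rounding; `confusion_metrics()` keeps full precision internally and
  rounds only for display and table comparison.

## Known limitations

* Only read-pair evidence is used; no de novo assembly verification is
  attempted (the supporting reads per candidate can be exported for an
  external assembler).
* The quasi-mapper tolerates mismatches only through the `r − k − 1`
  slop, not through scored alignment; heavily degraded reads lose
  sensitivity earlier than with a full aligner.
* Breakpoints are transcript-coordinate constructs lifted through the
  exon model; junctions inside introns or intergenic space are
  invisible by design.
* Fusions between isoforms of one gene (intra-genic rearrangements)
  are explicitly discarded by the same-gene rule.
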