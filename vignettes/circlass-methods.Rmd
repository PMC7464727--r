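---
title: "Classifying circular RNA junctions from chimeric alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying circular RNA junctions from chimeric alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlass)
```

## The problem

Total RNA-seq (ribo-depleted, no poly(A) selection) captures circular
RNAs alongside linear transcripts. A read that spans the circular
junction of a circRNA aligns to the genome in two segments in *inverted*
order: the first part of the read maps downstream of the second part, on
the same chromosome and strand. Splice-aware aligners report such reads
as chimeric alignments, and the breakpoints of the two segments identify
the genomic boundaries of the circularized transcript directly.

Most circRNA callers stop at exonic (back-spliced) circles and often
require the canonical GT/AG splice motif at the junction. That filter is
appropriate for back splicing but discards the two intron-derived
classes — lariat-derived intronic circRNAs (which begin at the intron's
5' base and end near the branch point, the 3' tail having been trimmed)
and intron circles (the full intron) — as well as circles arising inside
the single exon of mono-exonic, mostly non-coding genes ("sub-exonic"
circRNAs). `circlass` implements the full cascade: it selects circular
chimeric reads (CCRs), clusters them into loci associated with circRNA
production (LACs), and assigns each retained LAC exactly one class:

1. **exonic** — boundaries match annotated (or iteratively inferred)
   exon boundaries;
2. **lariat_intronic** — 5' intron base to a position strictly inside
   the intron;
3. **intron_circle** — exactly a whole intron;
4. **sub_exonic** — strictly inside the exon of a mono-exonic gene;
5. **unallocated** — everything else, kept for manual review.

## Read selection and coordinate conventions

A chimeric record is accepted as a CCR when both segments are on the same
chromosome and strand, in inverted order, each aligning at least
`min_segment = 15` nt (the aligner's chimeric segment floor), and the
junction code marks a within-read junction. Reads whose name appears in
more than one chimeric line (more than two segments, or conflicting
chimeras) are dropped entirely. Mates are treated as independent
single-end reads; mate identity is kept only for diagnostics such as the
mate-imbalance report. A conflicting mate alignment is deliberately *not*
a rejection criterion: sequencing is unreliable in GC-rich regions and
rejecting on the mate would deplete exactly the non-canonical classes.

Coordinates are 1-based inclusive throughout; BED input/output converts
at the system boundary only. Breakpoints in the chimeric dialect name
the first excluded base beyond each segment, so on `+` the circle is
`[acceptor_breakpoint + 1, donor_breakpoint - 1]`, mirrored on `-`.
Because aligner dialects differ and none of them document this reliably,
the offset pair is an explicit configuration value, and the simulator
round-trip test (planted circle in, identical interval out, both strands)
is what validates it — an off-by-one here would silently corrupt every
downstream boundary match.

The junction motif code carried by the aligner is passed through to the
report but never used as a filter: non-canonical junctions almost never
show GT/AG, so motif filtering would remove precisely the classes this
package exists to find.

## Clustering and the abundance threshold

CCR junctions are clustered by exact coordinates into LACs. A LAC is
retained when it has at least `min_ccr = 5` CCRs of which at least
`min_distinct = 4` are distinct. Distinctness is judged on the alignment
fingerprint (segment starts, segment CIGARs, read length): PCR
duplicates collapse, while two same-coordinate reads of different length
(the emulated dataset mixes 100 and 125 nt reads) count as distinct
molecules. The threshold is the guard against sporadic circularization
and duplicate-only support; both values are configuration keys.

## Iterative exonic labelling

Back-splice boundaries are matched exactly (same chromosome, strand, and
position; LAC start against exon starts, LAC end against exon ends).
Standard annotation labels a LAC when *both* boundaries are known. The
iterative strategy goes further: a LAC with exactly one known boundary is
also labelled, and its unmatched boundary is promoted as a putative novel
exon boundary; later rounds label LACs matching promoted boundaries,
promoting in turn, until a fixpoint. Rounds are batch-synchronous, which
makes the result independent of LAC input order.

Three design points were genuinely open:

* **Side typing.** A promoted novel boundary retains its side: a novel
  start only ever matches future LAC starts, a novel end only LAC ends.
  Without this, donor and acceptor roles could flip along a chain and
  label biologically nonsensical pairs.
* **Cross-gene pairing.** Boundary matching does not require both
  boundaries to come from one gene — read-through and undescribed
  transcripts are real; the matched gene ids are recorded as evidence
  instead.
* **Promotion support.** Novel boundaries are promoted unconditionally
  (`min_support = 0`); a minimum CCR support for promotion is exposed as
  a parameter for stricter runs.

The cascade runs over three prioritized exon lists (reference
annotation; curated lncRNA exons; novel exons from transcript assembly),
purging labelled LACs between lists. Novel boundaries never carry across
lists, so list priority is strict. A safety cap of 20 rounds guards
against pathological promotion cycles; the cap only trips when a round
past it still labels something, so convergent runs are never punished.

## Non-canonical classes

Within the post-exonic stage the evaluation order is intron circle,
then lariat, then sub-exonic — decreasing specificity, and the order
guarantees a full-intron LAC is never mislabelled as a lariat (its
trimmed tail would be 0, below `min_tail = 1`). Only introns of coding
genes are searched. For lariats, the 5' boundary must equal the intron's
first base (strand-aware) and the other boundary must lie strictly
inside; `tail_gap` records the trimmed 3' tail. No minimum circle size is
applied to intron-derived classes — the smallest real examples are under
100 nt, and a size floor was a known cause of missed loci. An optional
`branch_window` bounds the tail at a maximal branch-point distance; it
defaults to 0 (disabled) because no such bound is part of the method's
definition, but the knob exists for users who want standard branch-point
geometry (15–60 nt) enforced.

Sub-exonic circRNAs must lie strictly inside the single exon of a
mono-exonic gene (a boundary-touching locus belongs to the exonic
cascade) and be at least `min_size = 55` nt — below that, two 15-nt
segments plus microhomology slack make chimeric mappings unreliable.
Matches above `confident_size = 70` nt are flagged as the confident
subset. Per gene, sub-exonic LACs are partitioned into sets by single
linkage on strictly-positive interval overlap, and each set is summarized
as `count x min–max nt`.

## Junction sequences and alignment-shift merging

When bases at the circular junction are identical on both borders
(microhomology), the aligner can slide the junction point, so one
circularization event surfaces as several LACs a few bases apart.
`shift_equivalent()` declares two LACs equivalent when their start and
end differ by the same offset `s` (|s| ≤ `max_shift = 5`) and the |s|
bases after the acceptor boundary equal the |s| bases after the donor
boundary — exactly the condition under which the two coordinate pairs
describe the same circular molecule (their circle sequences are equal up
to rotation, which is what the test-suite oracle checks by brute force).
Events are single-linkage closures of this relation. The default
`max_shift` of 5 nt covers the few-base spreads seen in practice
(e.g. 10 LACs spanning 114–117 nt at one intronic locus) with margin.

Within an event, reads' junction-spanning fragments (k = 15 nt each
side) are aligned to the representative frame using the member shifts
and clustered; fragments are considered the same junction-sequence when
they agree outside a ±5 nt window around the junction, because reverse
transcriptase is error-prone near a 2'-5' link and near-junction
mismatches would otherwise inflate the circRNA count. The number of
clusters is the event's number of distinct circRNAs, so several LACs can
describe one circRNA and one LAC can hide two or three.

A separate consistency check covers circles shorter than half the read:
such a read must cross the junction twice, which a two-segment chimeric
record cannot represent; a single-passage read is flagged inconsistent
with the proposed circle size.

## The synthetic-data generator

The generator builds a two-chromosome toy genome (~125 kb) with
non-overlapping genes: 26 coding genes of 4 exons (120–300 nt exons,
250–900 nt introns), 4 other multi-exonic non-coding genes, 8
mono-exonic non-coding genes (100–600 nt), 6 lncRNA genes whose exons
appear only on exon list 2, and 4 "novel" genes only on list 3. It then
plants 200 circles — 120 exonic (including 10 with one undescribed
boundary and 2 three-circle chains exercising multi-round labelling), 40
lariats (branch position 15–60 nt from the intron 3' end, a simulator
choice following standard branch-point geometry), 8 intron circles, and
32 sub-exonic circles — and emits 8–40 junction-spanning reads per
circle as chimeric records, a SAM with read sequences, and an SJ table
of linear split reads.

The emitted noise mirrors the emulated dataset: read lengths 100/125 at
1:3, a 30% PCR duplicate rate, junction microhomologies of 0–3 nt
(planted into the genome, then surfacing as shifted LACs), a 20%
near-junction mismatch rate on lariat reads, and a 50% dropout of mate-1
reads mimicking GC-biased sequencing failure. Split positions are drawn
without replacement per read length so that distinct molecules have
distinct alignment fingerprints and only PCR duplicates collapse. Each
read length is kept below twice the circle size because a double
junction passage cannot be represented by a two-segment chimera — the
multi-pass check is therefore exercised on constructed cases. Decoy
records (wrong strand, wrong order, cross-chromosome, mate-encompassing
code, 14-nt segment) and deliberately duplicated read names exercise the
selection rules.

Every sampled quantity derives from a single seed; identical
configurations produce byte-identical files. What the generator does
*not* emulate: base-quality profiles, expression-level realism, rRNA
contamination, genuine branch-point sequence signals, and multi-isoform
gene models. Passing tests therefore demonstrate the correctness of the
selection/clustering/labelling logic under the stated noise model, not
performance on real sequencing artefacts.

## Numerical and degenerate-input choices

* Percentages and ratios round half away from zero (commercial
  rounding), which reproduces the printed-report conventions this
  package mirrors; the rounding rule is stated in the report header.
* A zero denominator is an error for percentages and mean-CCR-per-LAC,
  but a zero split-read count yields an infinite CCR/SR ratio (reported,
  not an error — the imbalance is the finding).
* Empty inputs flow through: an empty chimeric file produces a zeros
  report; empty exon lists are skipped by the cascade; an empty class
  reports no mean size rather than 0.
* When one LAC anchors introns of several transcripts, the smallest
  trimmed tail wins (most conservative lariat call).
* Ties in sub-exonic matching (a LAC inside two mono-exonic exons, which
  disjoint gene layouts make impossible but overlapping annotations may
  not) resolve to the first exon in annotation order.

## Problem sizes

The bundled tests run the full pipeline on a reduced simulation (≈60
circles) and the acceptance checks on the full 200-circle configuration;
oracle comparisons use 10,000 random loci for the threshold filter and
exhaustive shift × microhomology grids for the merge logic. A full
simulate-plus-classify cycle at the default configuration takes a few
seconds on one core.

## Known limitations

* The classifier trusts the aligner's breakpoints; it does not realign
  reads, and systematic aligner biases (beyond the modelled junction
  slide) propagate.
* Lariat calls are purely coordinate-based; no branch-point sequence
  model is applied, so an intron fragment that happens to start at the
  intron 5' base is indistinguishable from a true lariat remnant.
* Junction-sequence clustering assumes read sequences are stored in
  transcript orientation (as the bundled simulator and SAM convention
  provide); other conventions need a pre-pass.
* Anti-sense matching is intentionally not performed; all comparisons
  are strand-aware.
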