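---
title: "Methods: detecting regional DNA gain and loss from alignment nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting regional DNA gain and loss from alignment nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

Two genomes that diverged from a common ancestor differ by the DNA each
lineage gained (mostly transposon insertions) and lost (deletions). In a
pairwise alignment net, both kinds of event surface as the same object: a
*chain-gap*, sequence present in one genome with no counterpart in the
other. The entire pipeline is a procedure for deciding, for every chain-gap,
*which lineage's history explains it* — a gain on the hosting lineage or a
loss on the partner lineage — and then asking where in the genome, and when
in time, each kind of event accumulated.

Nothing in the package computes alignments; alignments are consumed, never
produced. All coordinates are 0-based half-open internally; net-format
start/size fields are converted on read, BED output is native. Minus-strand
query coordinates are converted to forward coordinates with an orientation
flag — the pipeline is coordinate-only and stores no sequence.

# Two complementary annotation rules

A chain-gap hosted (present) in genome A, absent from genome B, is resolved
two independent ways:

* **Ancestral-element method.** If the gap's A-sequence overlaps an
  *ancestral element* — DNA that outgroup species also align to — the DNA
  predates the split, so B must have deleted it: a **B loss**. Otherwise it
  is an **A gain**. This method is only as good as ancestral-element
  detection, which degrades in fast-evolving genomes whose ancestral DNA has
  diverged beyond alignability.
* **Recent-transposon method.** If the gap overlaps a copy of a transposon
  family classified as lineage-specifically active in A, the insertion
  machinery explains it: an **A gain**. Otherwise a **B loss**. This method
  is only as good as the family classification.

The rules fail in opposite directions, which is why both are computed and
cross-tabulated; method agreement per-bp is itself a quality statistic of a
run. Overlap always means ≥ 1 bp, and annotation is whole-gap (a gap is one
event), not bp-resolved — matching the event-level reading of the rules; a
bp-resolved variant would only differ on rare compound gaps.

# Ancestral elements and the depth threshold

Outgroup chain-blocks are merged per species and stacked into a coverage
track; depth counts *species*, not intervals. Low-depth coverage is enriched
for spurious alignments, so elements are called at depth ≥ d. The threshold
trades two bp-weighted error rates, estimated from data the inference never
uses directly:

* type 1 — the fraction of *known lineage-specific repeat* bp (a curated
  list, supplied as input) that elements overlap; this DNA cannot be
  ancestral, so any overlap is error;
* type 2 — the fraction of reference–query chain-block bp *not* covered by
  elements; chain-blocks are aligned between the two focal genomes and are
  taken as ancestral.

`select_threshold` picks the largest d whose step from d−1 removes more
type 1 fraction than it adds type 2 fraction — the marginal reading of the
trade-off; the alternative cumulative reading would saturate at the largest
threshold whenever early steps are large, which does not describe a
trade-off curve. Ties break toward smaller d. Fractions are bp-weighted
(totals are reported in Mb, so bp weighting is the consistent choice;
element-count weighting is a flagged alternative).

# The family classifier

Individual repeat copies are labelled ancestral iff they intersect ancestral
elements or chain-blocks. A two-class linear discriminant is then fitted on
copy rows with two features: the copy's percent divergence from its family
consensus (a molecular clock proxy for age) and the family-level bp
proportion overlapping ancestral DNA, broadcast to every copy. Whole
families are classified from their family-wise feature means; the family
decision, not the copy decision, drives downstream annotation, because
family activity windows are the biologically meaningful unit.

Design choices that were genuinely open:

* training on copy rows (with the family covariate) rather than family rows
  — copy rows weight large families more, which is appropriate when the
  decision consumes bp;
* empirical class priors rather than 50/50 — priors are logged on the model
  object; with strongly separated classes the choice is immaterial;
* family mean divergence is unweighted over copies; a bp-weighted mean is a
  one-line variant;
* the discriminant is fitted in closed form (class means, pooled covariance,
  w ∝ Σ⁻¹(μ₁−μ₀)) so the model object exposes exactly those quantities; a
  singular pooled covariance (e.g. a feature constant within classes, which
  happens on noise-free simulations) is a hard error directing the caller to
  a small diagonal ridge, whose amount is stored on the model.

# Placement and the synthetic genome

Annotated gaps hosted in the reference are inserted into the query at the
query-side coordinate shared by their flanking blocks. Placement runs from
the deepest net level upward and, within a level, by ascending anchor;
each placement shifts downstream synthetic coordinates by the gap's
reference-side length. Reference bases already placed by a deeper chain are
trimmed (nested nets duplicate gap bp across levels; every base is placed
once). The resulting synthetic genome satisfies, exactly and by
construction,

    synthetic length = query length + Σ placed gap lengths,

which the tests assert on every simulated instance. Query-hosted
annotations and masks are lifted through the placement map (`lift_to_synthetic`),
splitting any interval that spans an insertion point. Gaps whose flanking
blocks map to different query chromosomes (rearrangement edges) would be
skipped and logged; nets cannot actually express such a gap within one
chain, so the guard is defensive.

# Binning and the Gi* scan

Bins are 200 kb (the scale at which per-bin annotation totals stay below one
window width while preserving regional resolution); the trailing bin of a
chromosome may be shorter. A bin is retained only if ≥ 150 kb of it lies
outside assembly gaps and non-RBH masks; tallies are normalised to a full
window (raw × window / eligible bp). Because bins tile the *synthetic*
genome, an oversized placed gap spreads across bin boundaries instead of
saturating one bin.

Gi* is computed exactly as written in the README, with binary weights over
±3 bins (600 kb) on the same chromosome, self included (the Gi-star
convention — the focal bin carries weight 1; a toggle exists). X̄ and S are
global over all retained bins, not per chromosome, since n is defined as the
genome's bin count. Edge bins have truncated neighbourhoods; neighbourhoods
never cross chromosomes. p-values are two-sided normal (sidedness is a
documented option; calls split by the sign of Gi* afterwards, so the choice
moves thresholds, not ranks), BH-adjusted per category; hot requires
Gi* > 0 and q < 0.05, cold the mirror. A constant input (S = 0) yields
Gi* = 0 and p = 1 everywhere with a warning rather than NaNs — the honest
degenerate answer.

When hotspot calls are scored against *planted* clusters (simulation tests),
scoring is at region level: a maximal run of called bins counts as a true
positive iff it overlaps a planted cluster, and a cluster is recovered iff
some call region overlaps it. Bin-level precision is the wrong metric for a
neighbourhood statistic: bins one or two outside a strong 10-bin cluster
genuinely carry elevated neighbourhood sums, so Gi* must flag them, and
region-level scoring is how peak callers are conventionally evaluated.

# Enrichment and overlap tests

Feature enrichment standardises the observed hotspot-vs-rest difference in
per-bin feature means against a null built by permuting the hotspot/other
partition (group sizes preserved, without replacement, seeded). Bins with
missing feature values (e.g. an autosome-only recombination track) leave the
universe before permuting. The published display rule of masking |Z| ≤ 3 is
presentation, never computation. Hotspot–hotspot overlap uses the 2×2
partition of the bin universe with the two-sided Fisher exact p and the
sample cross-product odds ratio (0 and ∞ permitted, no continuity
correction); matrices of comparisons get one BH pass.

# Dating

Gains hosted in genome A are dated against A-related ingroup species
processed nearest-first: an event overlapping the nearest species'
alignment gaps post-dates that divergence (epoch 1, the youngest);
unsupported events fall in the oldest epoch. Losses from lineage A are dated
on the *partner* genome, where the lost DNA survives, against the same
panel processed farthest-first: a loss shared with (absent from) all
relatives is old; one overlapping no relative's gaps is the youngest. An
event overlapping several species' gap sets belongs to the first species in
processing order (sequential-removal semantics). Epochs are bounded by
consecutive divergence times, 0 MY at the young end and the reference/query
split at the old end; unmatched losses go to the youngest epoch — the
complement of the sharing logic, flagged as a convention. Rates are epoch
totals divided by epoch duration (Mb/MY).

# What the simulator emulates — and what it does not

`simulate_turnover` draws, per branch, family-structured insertions
(Poisson over bp × MY within each family's activity window, lengths 0.5–1 ×
consensus, per-copy divergence = clock × age + Gaussian noise) and
deletions (truncated lognormal lengths, mostly sub-kb), plus ancestral
repeat copies shared by descent. Defaults describe the study conditions a
mammalian comparison implies: a 50-Mb two-chromosome ancestor, a 90-MY
split, about a quarter of the ancestor gained and a quarter lost per
lineage, primate-like (0.30 %/MY) and rodent-like (0.45 %/MY) divergence
clocks, four and three staged ingroup species, and eight outgroups.
Alignments are emitted from known orthology as single-chain nets; outgroup
alignments can be degraded by whole-segment dropout and by exponential
boundary jitter into flanking gains (applied to a configurable fraction of
boundaries per species — spurious extension at *every* boundary would label
essentially all recent copies ancestral, which is noise no classifier should
be expected to survive), which is exactly the type 1 error substrate the
threshold selection needs.

Event footprints are kept disjoint on the ancestor with a minimum
separation, placed by the order-statistics (uniform-spacings) construction —
the uniform-conditional-on-disjoint layout, computed in O(m log m) rather
than by per-event rejection. Disjointness is what makes exact scoring
possible: every event is exactly one chain-gap. The cost is realism at the
margins, deliberately so:

* no nested events (a gain inside a gain, a loss clipping a gain), hence no
  hidden-event censoring; real turnover estimates are lower bounds for this
  reason, and the simulator's noiseless recovery says nothing about it;
* no compound gaps mixing a gain and an adjacent loss in one record;
* outgroups are idealised as the ancestor (no outgroup-private events);
  ingroups carry exactly the host lineage's older events;
* no rearrangements, inversions or duplications — all chains are positive
  strand and collinear (the parser supports minus-strand and nested nets,
  exercised by hand-built fixtures instead);
* no sequence, hence GC content enters only as a per-block covariate.

Passing the end-to-end tests therefore demonstrates that the *machinery* is
correct (coordinates, rules, statistics), not that real nets are this clean.

# Numerical and reproducibility choices

Interval algebra delegates to IRanges/GenomicRanges behind thin 0-based
wrappers, so merging, intersection and coverage carry no hand-rolled edge
cases. Seeds: `simulate_turnover` and `permutation_enrichment` take explicit
seeds and restore the caller's RNG state. The pipeline is deterministic
given its input files; re-running a directory reproduces identical
annotations, bins and calls (asserted in tests). JSON manifests record
parameters, per-stage bp tallies and file provenance.

Problem sizes in the test-suite were chosen to exercise every scale the
statistics need: toy fixtures (≤ 1 kb) for hand-traceable oracles, 1.3-Mb
simulations for fast end-to-end property checks, one 50-Mb simulation for
full-scale recovery, 5000-bin scans for hotspot calibration, and 200 × 2000
permutation replicates for Z-score calibration.

# Known limitations

* The ancestral-element method under-calls in fast-evolving genomes — by
  design it can only see ancestry that still aligns; the cross-tab makes
  the resulting method disagreement visible rather than hiding it.
* Whole-gap annotation assigns compound gaps entirely to one category.
* The dating procedure is parsimony-based: events erased by later events on
  the same lineage are invisible, and rate estimates are lower bounds.
* `error_profile` needs a non-empty curated lineage-specific repeat list;
  with an empty list the type 1 column is identically zero and threshold
  selection degenerates to depth 1 (correct, but then elements should be
  reviewed by eye).
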