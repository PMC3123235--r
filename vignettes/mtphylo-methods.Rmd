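---
title: "Methods: rule-driven curation and parsimony annotation of mtDNA phylogenies"
author: "mtphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-driven curation and parsimony annotation of mtDNA phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtphylo)
```

## Overview

mtphylo turns a raw collection of mitochondrial-style genome sequences
into an annotated phylogeny through a fixed sequence of stages, each of
which both transforms its input and tests it:

1. **Quality control** — length classes, ambiguity accounting, N-run
   detection, duplicate compression (`run_qc`).
2. **Rotation correction** — detection and automatic repair of circular
   start-point displacements (`detect_rotation`, `correct_rotation`).
3. **Partitioned alignment** — reference-guided splitting into
   structural units, per-unit alignment, overlapped merge
   (`partition_align`).
4. **Distance screening** — parsimony edit distances and group-wise
   outlier flags (`distance_matrix`, `group_outliers`).
5. **Tree inference** — neighbor joining, optional bootstrap and
   majority-rule consensus, outgroup rooting (`neighbor_joining`,
   `majority_consensus`, `root_by_outgroup`), or an external ML engine
   through a subprocess adapter.
6. **Annotation** — generalized Fitch parsimony labeling, event
   classification and tree statistics (`annotate_tree`).

Restrictive stages feed flags back into the dataset's provenance log.
Low-risk repairs (rotation, duplicate compression) are applied
automatically; exclusions beyond hard rule violations require the
`auto_exclude` opt-in, so a human stays in the loop exactly where the
decision is not mechanical.

## Quality rules and their parameters

The length rules encode the empirical structure of complete human mtDNA
submissions. Defaults (all configurable via `qc_config()`):

| parameter | default | meaning |
|---|---|---|
| `strict_length_range` | [16550, 16600] bp (closed) | accepted full genomes |
| `max_length` | 16600 bp | hard ceiling; longer records are intrusions |
| `control_region_vacuum` | [15600, 16300) bp | no coherent sequence occurs here; below it = control region missing |
| `review_ranges` | [16300, 16550) bp | retained but flagged for inspection |
| `ambiguity_threshold` | 5 | max tolerated ambiguous positions |
| `n_run_min` | 10 | minimal N-run flagged as unsequenced stretch |

The strict band is closed because the colon-notated empirical range is
inclusive at both printed endpoints; all other bands are half-open
`[lo, hi)` so adjacent intervals tile without gaps. The ambiguity
threshold of 5 reflects the observation that a handful of ambiguous
calls per genome is routine sequencing noise while larger counts
correlate with systematically incomplete records; `n_run_min = 10` is
far above isolated no-calls and well below the shortest deliberately
unsequenced stretch one encounters in practice. Review-range sequences
are *kept* by default — known legitimate deletions live there — and
dropped only under `strict_exclude`.

Duplicate equality is exact string equality of raw residues. An
ambiguity-aware equality (N matching anything) would conflate genuinely
different genomes and make the compression non-transitive, so it is
deliberately not offered.

The historical placeholder `N` at canonical position 3107 of the rCRS is
kept as an `N` residue with a reference-level `false_gap` annotation; no
extra symbol is invented, because none exists in the IUPAC alphabet.

## Rotation correction

A genome linearized at the wrong origin places canonical position 1
mid-string; left untreated it shreds the multiple alignment with huge
terminal gap blocks. `detect_rotation` seeds candidate displacements with
12-mers sampled from the reference, verifies each candidate by ungapped
positional identity, and accepts the best offset only when it beats the
unrotated identity by 5 percentage points. The margin makes the detector
conservative: an unrelated sequence, or an unrotated sequence with a few
percent divergence, yields "no rotation" because no candidate clears the
gain requirement. Downstream algorithms then work on linearized,
rotation-corrected sequences; circularity survives only as an annotation
flag.

## Partitioned alignment

Aligning thousands of ~16.6 kb genomes jointly is unnecessary: the
molecule's gene structure provides natural split points. Each sequence is
aligned once against the reference (cached thereafter), unit boundaries
are mapped through that alignment, and each unit is aligned separately.
Applied to the bundled rCRS feature table the partition yields 50 units:
37 genes, 11 non-coding gaps inside the coding region, and the control
region split in two by the numbering origin. Where annotated genes
overlap (e.g. ATP8/ATP6), both units carry the shared interval and the
merge keeps the left unit's columns after verifying residue agreement —
a disagreement is a hard error naming the sequence and unit pair, never a
silent preference, because it indicates an inconsistency between two
independently computed alignments of the same residues.

Two scoring presets exist (`scoring_scheme()`): the default *linear*
scheme (match 0, mismatch 1, gap 1) under which the optimal global
alignment score equals the per-column parsimony distance, and an
*affine* preset (`gap_open = 3`, `gap_extend = 1`). Reference-guided
splitting and unit alignment use the affine preset: under linear costs
the placement of a deletion block is frequently co-optimal with
scattered placements (any 18 gap columns cost 18), and an aligner may
legitimately scatter residues across unit boundaries; affine costs make
the single-block solution uniquely optimal. Distance computation keeps
the linear, per-column semantics.

The internal unit aligner is a reference-anchored star alignment: every
slice is aligned pairwise to the unit's reference residues and merged on
the shared anchor coordinates. It is exact per pair, deterministic, and
adequate for the high-identity regime mtDNA units live in; for diverged
or indel-rich data any FASTA-in/FASTA-out tool can be plugged in as the
engine (`engine = "mafft"`), and the test suite checks the internal
engine's sum-of-pairs cost stays within 20% of mafft's on generated
units. Rows missing a unit (e.g. flexible genomes without a control
region) are padded with the unsequenced marker `?`, which is distinct
from the biological gap `-`: padding expands to the full Fitch state set
and can never generate events, deletions can.

Gap runs in coding units are classified by the codon rule: `codon_full`
iff the run length is a multiple of 3 *and* the run starts on a codon
boundary per the unit's reading-frame offset; everything else is a
`frameshift`. A 3 bp gap starting mid-codon is deliberately a frameshift
— it disrupts two codons even though it preserves downstream frame; the
per-boundary rule keeps the call local and checkable.

## Distances and outlier screening

Parsimony edit distances come in two modes: `per_column` (differing,
not-both-gap columns; a metric on fixed-length rows) and `single_event`
(substitution columns plus one event per maximal gap run). A column
contributes nothing when the two IUPAC sets intersect, so ambiguity never
inflates distance; `skip_ambiguous` additionally drops such columns
per pair, reproducing the "unambiguous sequences only" restriction under
which distance distributions are cleanest.

Group-wise screening flags a sequence when its median intra-group
distance exceeds the group median of such medians by more than
`k = 5` robust spreads. Because these distances are small integer counts,
the MAD of the medians can collapse to ~1 in tightly clustered groups,
which would flag ordinary long-branch individuals; the spread is
therefore floored at `sqrt(median)`, the Poisson counting-noise scale.
The screen assumes groups of at least ~20 reasonably homogeneously
sampled members; in very small or deeply structured groups a basal clade
can legitimately exceed the threshold, which is a sample-size artifact
users should expect (flags mean *review*, not *exclude*). Statistically
separated clusters (distinct species) must be screened separately; the
separation report (min inter-group vs max intra-group distance) makes
the check explicit.

## Trees

Internal inference is neighbor joining on the chosen distance matrix:
deterministic, exact on additive matrices, and fast at desk scale.
Maximum-likelihood engines are supported strictly as subprocess adapters
(FASTA in, newick out) — the package does not reimplement likelihood
machinery, and all downstream annotation is engine-agnostic. Negative NJ
branch lengths are clamped to zero with a count recorded in the
`clamped` attribute.

Bootstrap resampling draws columns uniformly with replacement under a
fixed seed; the majority-rule consensus retains bipartitions with
frequency strictly greater than the threshold (default 0.5, the
conventional choice when no threshold is dictated) and reports the
frequency as support. Supports live on the consensus rather than being
mapped onto a best tree; both objects are available. Rooting uses a
designated outgroup that must be monophyletic in the unrooted tree —
a non-monophyletic outgroup is an error that names the conflicting
leaves, since silently rooting on a non-clade misstates ancestry.

## Fitch annotation

`fitch_label` runs generalized Fitch parsimony per column over the
five-state alphabet {A, C, G, T, −}. Leaf IUPAC codes enter as state
subsets (N = all four bases); unsequenced padding `?` enters as the full
five-state set. The bottom-up pass intersects child sets (union, +1
change, when disjoint); the top-down pass resolves the root to its
set's first member in the fixed order A < C < G < T < − and propagates
parent states downward when possible. The fixed order is an arbitrary
but deterministic tie-break: any choice yields the same score, and
reproducible annotation matters more than which co-optimal labeling is
reported.

Event flags:

* **conserved** — column dominant fraction α above the threshold
  (default 0.95, with 0.99 a common stricter companion). α's
  denominator counts only unambiguous, non-gap residues, so that the
  profile reflects true polymorphism rather than data quality; a
  count-all-rows denominator is available.
* **back_mutation** — the event's target state was the source state of
  an earlier event at the same column on the same root path. This
  path-scoped reading covers any reversal during descent; the stricter
  root-state-only variant is available (`scope = "root"`).
* **ambiguous** — the event enters a leaf whose observed symbol at that
  column is not a single concrete state. Internal candidate-set unions
  at polymorphic columns are *not* ambiguity — treating them as such
  would mark every deep polymorphism ambiguous — so the flag is anchored
  to observed data.
* **indel** — either endpoint is the gap state. Each character is
  treated independently: a 3 bp deletion appears as three single-column
  events, and no unification into one event is attempted at the
  annotation level.

A note on locality of ambiguity: widening one leaf's state set can only
change bottom-up candidate sets on that leaf's root path (no other
node's inputs change), and can never raise the score — both are asserted
in the test suite. The *resolved* states of nodes hanging directly off
that path can occasionally flip between co-optimal labelings, so the
effect of an ambiguous leaf is local but not strictly confined to its
pendant path.

Statistics: the cross-tab rows are unambiguous / ungapped (the
unambiguous events without indels, a sub-row) / ambiguous, columns are
conserved / back-mutation / both / remaining, with totals obeying
inclusion–exclusion; branches carrying more than 50 events are review
outliers (in curated real data such branches are almost always single
anomalous leaves); generation points count the distinct branches on
which a mutation type arises, with the type keyed by position or by
position plus states; and the perfect-phylogeny bound
Σ<sub>columns</sub>(distinct unambiguous symbols − 1) is the floor no
tree can beat, attained exactly when no position mutates twice.

## The synthetic-data generator

The generator is first-class, tested code: it is the source of ground
truth for every stage. Its default genome is 2000 bp with a 300 bp
control region split 100/200 around the origin, six genes (four
protein-coding, lengths multiples of 3) and two non-coding gaps — ten
units, structurally faithful to the real 50-unit scheme while small
enough for the exhaustive oracles. Trees are Yule (random tip splits)
with exponential branch lengths of mean 0.1; substitution counts per
branch are Poisson(20 × length) under a uniform-rate model, giving
pairwise distances of a few tens of counts on 2000 sites — the same
regime, relative to genome length, as real intraspecies mtDNA data.
The deliberately simple uniform-rate model exercises the parsimony
machinery; it does not emulate GTR-style rate heterogeneity, so passing
tests say nothing about model adequacy on real data, only about the
correctness of the curation and annotation algorithms.

Defects are injected at requested counts into distinct victims:
rotations (offset 100), control-region truncations (below the scaled
vacuum bound), N-runs (length 25), exact duplicate copies (ids suffixed
`_dup` so the original stays the representative), divergent intrusions
(60 extra substitutions), and overlong insertions. Background ambiguity
injection is a rate, not a defect, and is capped at the QC ambiguity
threshold per sequence so that only deliberate defects cross curation
thresholds — that cap is what makes registry-exact recovery a
well-posed test. For the same reason the generator guarantees distinct
leaf sequences (coincident leaves receive a recorded private
substitution): real densely sampled data contain ~10% natural
duplicates, but ground-truth recovery requires the registry to be the
only source of duplication.

With recurrence disabled every reference position mutates at most once
tree-wide, so the true tree's Fitch score equals the number of generated
events and the perfect-phylogeny bound is attained — both are asserted.
`force_revert` plants one x→y / y→x pair on a root path to exercise
back-mutation detection deterministically.

## Numerical and degenerate-input choices

* Pairwise alignment is delegated to `Biostrings::pairwiseAlignment`
  (batched per subject for speed) with IUPAC-set-aware substitution
  scoring; its deterministic traceback supplies the tie-break.
* All-gap conservation columns have α = NA and are excluded from
  profile summaries.
* Empty unit slices (deleted or unsequenced units) are flagged, not
  errors; units with fewer than two nonempty slices fall back to a
  single pairwise anchor alignment or are skipped.
* `run_qc` recomputes its log section idempotently: re-running on its
  own output changes nothing.
* Problem sizes in the test suite (leaf counts of 6–30, 2000 bp
  genomes, tens of seeds per property) were chosen so the exhaustive
  oracles — full enumeration of ancestral assignments, all alignments
  of short strings, all rotations — remain exact rather than sampled.

## Known limitations

* The internal star aligner anchors on the reference; for units where
  the reference is highly atypical of the sample its alignments can be
  suboptimal — use an external engine there.
* Back-mutation counts depend on which co-optimal Fitch labeling the
  deterministic tie-break selects; alternative tie-breaks can shift
  individual flags without changing the score.
* The distance-outlier screen is a review aid calibrated for
  reasonably homogeneous groups of ≥ ~20 sequences, not a significance
  test.
* Circularity is handled only as start-point correction; alignments and
  distances are computed on linearized sequences.
* No likelihood-based inference or ancestral reconstruction is
  implemented; ML engines are adapters only.
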