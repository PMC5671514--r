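---
title: "Methods: pri-miRNA gene-model annotation and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pri-miRNA gene-model annotation and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the classification
and assignment rules, the counting and testing machinery, the numerical
choices behind them, and what the synthetic-data generator does and does
not establish about real data.

## Positional classification

The unit of all positional logic is the 1-based, both-ends-inclusive
genomic interval, matching GFF3/GTF conventions: `overlap_bp()` counts
shared bases and `gap_bp()` counts bases strictly between two intervals,
so book-ended features have gap 0 without sharing a base. All
classification runs on full gene spans, not exons, because gene records
are the unit at which host-gene relationships are annotated; and strand is
recorded but ignored by default, because pri-miRNA transcription need not
match the orientation of a neighbouring or host gene. A `strand_aware`
flag restricts comparisons to same-strand features for users who want it.

Classification is two-pass. The hairpin-level pass (`classify_hairpin`)
can yield G1 (intergenic), G2 (nearest coding gene 1–400 bp away), G3A
(hairpin overlaps a coding gene) or G4 (overlaps a non-coding gene); the
model-level pass (`classify_model`) can additionally yield G3B, the case
where the assembled model — but not the hairpin — reaches into a coding
gene. Features satisfying several definitions are resolved by the fixed
precedence G3A > G3B > G4 > G2 > G1: overlap evidence outranks proximity,
and coding overlap outranks non-coding overlap. The precedence order is a
design decision of this package; the group definitions imply but do not
state one.

Two further boundary decisions are worth making explicit:

* the near-gene window is `gap_bp` in `[1, 400]` inclusive at both ends
  (gap 400 is G2, gap 401 is G1), the window width being the `g2_window`
  parameter;
* a gap of exactly 0 (book-ended, no shared base) is neither overlap nor
  within the 1–400 window, hence G1. This is a faithful reading of
  "1–400 bp away"; it affects only zero-width gaps, which do not occur in
  practice.

The G2 distance is measured on whichever interval is being classified —
the hairpin in pass one, the model span in pass two — since each pass asks
the question of its own interval.

## Model assignment and merging

Each hairpin receives exactly one gene model (`assign_model`):

1. a G3A hairpin adopts the full span of its host coding gene
   (`host_gene`); if several genes overlap the hairpin, the largest base
   overlap wins, and an exact tie picks the leftmost gene and records a
   `host_gene_tie` conflict flag rather than guessing silently;
2. otherwise, a hairpin matched to a transcript prediction adopts the
   prediction's span (`predicted_transcript`); matching requires at least
   1 bp of overlap, the prediction with the largest hairpin overlap wins,
   and ties break deterministically by leftmost start then lexicographic
   id;
3. otherwise the model is the hairpin annotation itself
   (`hairpin_fallback`).

Models sharing a source — the same prediction or the same host gene —
merge into one model carrying both hairpins. Merging never happens on mere
proximity. A prediction claimed by more than two hairpins keeps the two
with the largest overlaps; the remainder fall back to their hairpin
coordinates with a `prediction_overloaded` flag, since models with more
than two member hairpins are not part of the data model. Final models
whose intervals overlap models from a different source are flagged
(`overlaps_model:*`) and left untouched: resolving such conflicts requires
inspecting read dispositions, so the package reports them for manual
review instead of editing coordinates automatically.

Every report enforces two bookkeeping identities at the totals level:
final models = predicted-derived + reference-derived, and hairpins = final
models + two-hairpin models. Per-row hairpin counts are informative only,
because a hairpin's first-pass label can legitimately differ from its
final model's group (every G3B model starts as a G1/G2 hairpin).

## Read counting

`count_reads` reimplements the quantification semantics rather than
delegating to a counting library, because the semantics are part of the
contract: only mapped, primary records (secondary and supplementary
flags excluded) with MAPQ ≥ 10 are considered — multi-mapping reads
thereby count once, through their primary record — and each read is
assigned to the feature with the largest number of overlapping bases.
Equal-overlap ties are deliberately left ambiguous and uncounted.
Overlap is measured on reference-consuming CIGAR operations with
deletions (`D`) counted as overlap and skips (`N`) as gaps; insertions
and clips consume no reference. Paired records sharing a read id are
pooled and counted as one fragment by default (`mode = "fragment"`),
with `mode = "read"` available for per-record counting; whether the
original analyses counted reads or fragments for paired libraries is not
documented, so the choice is exposed. All category counts (assigned,
ambiguous, no-overlap, below-MAPQ, not-primary, unmapped, unknown
chromosome, malformed CIGAR) are returned and partition the input, which
the tests verify.

## Differential expression

The engine is a two-group exact negative-binomial conditional test with
TMM normalization. It deliberately approximates the original
quasi-likelihood and likelihood-ratio analyses with a single, simpler
test whose correctness is established distributionally on simulations —
numerical replication of any published implementation is a non-goal.

*Normalization.* `tmm_factors` implements the trimmed mean of M-values:
pairwise against a reference sample (the one with the most typical
upper-quartile expression), genes expressed in both samples contribute a
log2 expression ratio; the most extreme 30% of ratios and 5% of average
expressions are trimmed; the factor is the inverse-variance weighted mean
of the rest, and factors are rescaled to multiply to 1. The test suite
cross-checks the implementation against the reference implementation in
`edgeR` (< 0.5% discrepancy) — the cross-check is a test, not a runtime
dependency.

*Library equalization.* The conditional test requires equal library
sizes. Counts are scaled to the geometric mean of the TMM-adjusted
effective library sizes; group sums are rounded to integers for the
conditional enumeration. This linear scaling is simpler than quantile
matching and is adequate at the library-size ratios typical of a designed
experiment; it is exact when libraries are already equal.

*Dispersion.* Three modes. `fixed_bcv`: dispersion = BCV², with
BCV = 0.4 as the conventional choice for designs without replicates
(dispersion 0.16). `common`: the maximizer of the summed conditional NB
log-likelihood (each group's counts conditioned on its group total, a
form that cancels the mean parameter), found by 1-D search of the
log-dispersion on [1e-6, 10]; only groups with ≥ 2 samples contribute,
and a design with no replicated group is an error directing the caller to
fixed-BCV mode. `tagwise`: each feature maximizes its own conditional
likelihood plus `prior_weight` (default 10) times the ensemble-average
likelihood, interpolating between the per-feature MLE (weight 0) and the
common value (weight ∞). The ensemble term is precomputed on an 81-point
log-spaced grid and spline-interpolated, so per-feature optimization
stays cheap.

*The test.* For each feature with group sums *a* and *b* over *n₁* and
*n₂* equalized libraries, the conditional distribution of *a* given
*t = a + b* is computed from the NB convolution (group sums of NB(μ, φ)
counts are NB with mean *nμ* and dispersion *φ/n*), and the two-sided
p-value is the total probability of all splits of *t* no more likely than
the observed one. As φ → 0 this reduces to the exact conditional Poisson
(binomial) test, which the tests verify against an independent
enumeration oracle to 1e-9. Features with zero total get p = 1 and
log2FC = 0. Fold-changes use normalized group means with a prior count of
0.125 (any small constant would do; the value avoids infinite ratios and
is documented here). Average expression is reported as log2 CPM.
Benjamini–Hochberg adjustment is delegated to `stats::p.adjust`.

*Calibration.* On a seeded null simulation (2,000 features, BCV 0.4,
2 vs 2, 20M-read libraries) the fraction of p < 0.05 is ≈ 0.05 (slightly
conservative from discreteness), and a 4-fold effect at mean 100 is
detected at FDR < 0.05 in well over half the affected features — both
asserted in the test suite at those problem sizes, which were chosen as
the smallest at which the Monte-Carlo bands in use are reliable.

## Group-level analysis

Detection requires ≥ 4 reads accumulated over all libraries of one
experiment. Group behaviour is assessed by a one-sided Wilcoxon rank-sum
test of each group's log2 fold-changes against a background set; the
background defaults to all protein-coding (non-pri-miRNA) features in the
DE table, a choice this package fixes explicitly because no canonical
comparison set exists — it is exposed as a parameter. The Wilcoxon
p-value comes from `stats::wilcox.test` (exact enumeration for pooled
samples ≤ 20 without ties, normal approximation with tie and continuity
corrections otherwise); published per-group p-values from equivalent
analyses are therefore reproducible in distribution but not bit-for-bit,
since the original background set and tie handling are unknown.

Cross-experiment comparison classifies each common detected model by the
sign of its log2 fold-change in each experiment; exact zeros and missing
values are excluded with counts, and the 2×2 cells always sum to the
number of features entering — a conservation identity the class enforces.
An optional FDR filter applies to the replicated experiment only,
mirroring the situation where the second experiment lacks replicates.

## The synthetic-data generator

`simulate_annotation` places units (background genes and one
hairpin-scenario per group) along a single chromosome separated by
spacers wide enough (> extension + window) that no feature of one unit
can influence another unit's classification. Within units: G2 gaps are
drawn uniformly on [1, 400]; G3A hairpins sit strictly inside their gene;
G3B hairpins sit 401–600 bp from a gene with a prediction always reaching
into it; G4 hairpins sit inside a non-coding gene; two-hairpin units
place two intergenic hairpins under one prediction. Predictions extend
hairpins by 50–300 bp, capped on the gene side for G2 so the model stays
inside the window. Truth labels are therefore unambiguous by
construction, and the generator re-derives every label by direct
coordinate arithmetic before returning, failing loudly on any
inconsistency. A `boundary_cases` flag appends hairpins at gaps exactly
400 and 401 for edge testing. All generators are bit-reproducible from
(config, seed); counts use a seed offset so annotation and counts draw
from distinct streams.

`simulate_counts` draws NB counts with mean
`baseline_cpm × 2^(lfc × mutant) × libsize / 1e6` and variance
`μ + BCV²μ²`; `simulate_alignments` writes uniquely placed primary
single-end alignments (MAPQ 50) uniform within their source feature, so
the counter recovers requested numbers exactly on disjoint features.

Default conditions were chosen once to mirror a two-genotype,
two-replicate embryo transcriptome design at desk scale: 31 hairpins plus 2 two-hairpin pairs across the five groups, 150
background coding genes, prediction detection probability 0.6, four
libraries of 2×10⁷ reads (two wild type, two mutant), BCV 0.4, log-normal
baseline expression (median 5 CPM), group log2 fold-changes of
2/1.5/0.5/2.5/1.5 for G1/G2/G3A/G3B/G4 — strong up-regulation for the
clean intergenic and predicted-model groups, weak for G3A where the gene
model is the host gene and mostly measures host expression — and
background fold-changes N(0, 0.5), reflecting that a biogenesis mutant
perturbs much of the transcriptome.

What passing the closed loops does **not** show about real data: the
generator enforces unambiguous spacing, single-exon-style predictions and
uniquely mapped single-end reads. Real annotations contain nested and
overlapping genes, ambiguous prediction–hairpin relationships, multi-exon
models whose introns span genes, and multi-mapping reads; the classifier
and counter handle these by the documented precedence, tie and flag
rules, but the 100%-recovery properties only certify the rules'
implementation, not their biological sufficiency. Likewise the NB
simulation matches the test's own model family, so calibration results
certify internal consistency, not robustness to model misspecification.

## Known limitations

* Overlap is gene-span based; exon-aware classification is out of scope.
* The exact NB test is a deliberate approximation; analyses requiring
  quasi-likelihood F-tests should use a dedicated GLM framework.
* Conflicting overlapping models are flagged, never auto-resolved; the
  handful of cases needing coordinate edits in any real annotation run
  remain a manual step.
* No FASTA/sequence handling, hairpin discovery, or transcript assembly:
  the pipeline starts from an existing annotation, assembler output and
  alignments.
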