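---
title: "Graded chromatin borders and domain states: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded chromatin borders and domain states: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromborders)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the
design decisions taken where the design was genuinely open.

## Data model and conventions

All coordinates are 0-based half-open (BED dialect) everywhere; the only
unit conversions are inside the bedGraph/BED writers, which keep the same
convention. A fragment record `(chrom, start, end, barcode, count)`
represents two Tn5 insertion events, at `start` and `end - 1` — 10x-style
fragment files are already shift-corrected, so no +4/−5 adjustment is
applied. Count matrices are built by crediting each fragment's count to
the bin of each terminus (`bin = floor(pos / width)`), so the matrix
total is exactly twice the summed fragment counts of retained barcodes —
a conservation law the tests assert. Insertion-based binning (rather
than midpoint or full-overlap) matches the accessibility-field convention
that the informative event is the transposase insertion.

## Per-cell QC

TSS enrichment is the mean insertion rate (insertions per bp, pooled
over TSSs) within ±100 bp of a TSS, divided by the mean rate in the
outermost 100 bp of the ±2-kb window. The exact windows used by the
established per-cell QC tools are not standardized; these constants are
exposed (`window`, `flank`) and chosen so the score is brute-force
checkable: a uniform insertion process scores 1 by construction, and a
cell with zero background signal scores 0 with a flag rather than
dividing by zero. The retention filter is strict on both axes —
TSS enrichment > 7 *and* unique fragments > 3,000 — so a cell at exactly
either threshold is rejected; this matters for reproducing
cut-off-dependent cell counts. The synthetic cells simulated here carry
two orders of magnitude fewer fragments than real nuclei, so the demo
pipeline applies demonstration thresholds while `qc_filter()` keeps the
stringent defaults.

## Pseudobulk tracks and smoothing

Group tracks are per-bin sums over the group's cells scaled to counts
per million of the group total, so every track sums to 1e6 and is
invariant to uniform count rescaling. CPM was chosen as the default
because the upstream normalization behind published "normalized signal"
tracks is rarely stated; any per-modality scale cancels both in the
robust-z border detector and in the fold-over-baseline domain rule.
Smoothing is a discrete Gaussian (kernel truncated at 4σ and
renormalized) with symmetric reflection at the track ends, which
conserves total mass exactly for the symmetric kernel; constant tracks
pass through unchanged and non-negative input stays non-negative.

## Border detection

Given a per-modality track over the analysis locus, the detector:

1. Gaussian-smooths with σ (default 3 bins of 2 kb);
2. takes first differences between adjacent bins, so a boundary lives on
   a bin edge;
3. converts differences to robust z-scores;
4. keeps local |z| maxima with |z| ≥ threshold (default 4);
5. greedily merges candidates closer than the minimum separation
   (default 5 bins), keeping the largest |z|, ties to the leftmost.

The one numerically delicate step is the robust scale in (3). Taking
the MAD of the *smoothed* differences over the locus fails on exactly
the loci this method is for: smoothing spreads each transition over
roughly ±2σ bins, so a ~130-bin locus with five transitions has nearly
half its differences sitting on transition slopes, and the MAD measures
typical slope rather than noise — inflating the denominator several-fold
and suppressing genuine moderate steps. The package therefore estimates
the noise from the MAD of the *raw* (unsmoothed) differences, where each
transition occupies a single bin and >95% of differences are pure noise,
and propagates that estimate through the smoothing kernel analytically
(for white noise, the ratio of smoothed-difference to raw-difference
standard deviation is `sqrt(sum(diff(kernel)^2) / 2)`). Degenerate
inputs fall back gracefully: for piecewise-constant tracks the smoothed
MAD is used, and for fully noiseless tracks the scale is set from the
largest change so every step clears the threshold while relative
amplitudes — and hence tie-breaks — are preserved.

Counts are Poisson-like, so their variance scales with the mean; a
single global noise scale would over-detect inside high-signal segments.
The pipeline wrapper `call_borders()` therefore applies the square-root
variance-stabilizing transform to each CPM track before detection
(`transform = "sqrt"`, the default; `"none"` is available). The
transform commutes with uniform rescaling, so grades remain invariant to
any per-modality scale factor.

Local maxima are defined as strictly greater than the left neighbour and
at least the right neighbour, which selects the leftmost bin of an exact
plateau; the greedy merge visits candidates in decreasing |z| with
position as tie-break, so two equal steps closer than the minimum
separation resolve deterministically to the leftmost.

## Graded borders and domain states

Per-modality boundaries are aggregated by single-linkage clustering of
their positions, chaining while the gap is at most the cross-modality
tolerance (default 2 bins). Within a cluster each modality contributes
at most once — its largest-amplitude member — and the border grade is the
number of distinct supporting modalities. Published figure legends name
only the medium (two-modality) and strong (three-modality) grades; a
single-modality border is documented here as *weak*, the remaining
grade. Direction is recorded but not used for grading. The consensus
position is the amplitude-weighted mean of the kept members ("support-
weighted": stronger boundaries pull the consensus harder).

Domains between consecutive borders are labelled from per-modality mean
CPM expressed as fold over a user-supplied baseline (flanking) interval:

- **silenced**: H3K27me3 fold ≥ 4 and ATAC fold < 2;
- **primed**: ATAC fold ≥ 2, H3K27ac fold ≥ 2 and H3K27me3 fold ≥ 1.5;
- **inactive**: otherwise.

The silenced rule is evaluated first, so heavy repression with residual
acetylation does not leak into "primed". The thresholds encode the
ordinal statements the analysis rests on — primed chromatin carries
repressive signal distinctly above the flank but far below the silenced
block — and are all arguments with the defaults above. A zero baseline
in any modality raises an error instructing a pseudocount rather than
silently producing infinite folds.

## Within-cell joint-mark analysis

Because both histone marks are captured in the same nucleus under one
cell barcode, per-cell regional signal can be compared across marks.
Signal is depth-normalized per cell and per modality (counts per
thousand of the cell's total in that modality) because the two marks
have systematically different depths. The two-group split on regional
H3K27me3 uses one-dimensional 2-means with deterministic initialization
at the 10th and 90th percentiles — a reproducible, refusable alternative
to an eyeballed sort: identical values, or clusters that collapse,
return a refusal with a diagnostic instead of an arbitrary split. Group
1 is always the higher-signal group, so labels are invariant to input
order; the mean silhouette width is reported as a separation diagnostic.
Equality of H3K27ac across the groups is assessed with a two-sided
label-permutation test on the difference of group means, with
`p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)` so p is never zero.

## Contact-matrix analytics

Balancing is plain iterative correction: divide by row sums until every
unmasked row sums to the chromosome mean, weights normalized to mean 1,
convergence when the maximum relative row-sum deviation is below 1e-5
(cap 200 iterations; on non-convergence the best iterate is returned
with the residual in a warning). Rows with under 2% nonzero entries are
masked first, and masked bins are excluded from every downstream
statistic — expected profiles, O/E, insulation and pileups never average
NaNs in.

The distance-decay expected value is the mean over unmasked pixels of
each diagonal; O/E is the elementwise ratio. The compartment
eigenvector is the leading eigenvector of the Pearson correlation matrix
of log O/E, with the sign anchored to correlate positively with a
supplied reference track (accessibility is the natural choice, since
active compartments correspond to accessible chromatin); constant input
is reported as undefined rather than returning an arbitrary vector.

Insulation follows the diamond convention: at bin *b* the score is the
sum of contacts between the *w* bins upstream and the *w* bins
downstream (*w* = window / bin, default 100 kb on 10-kb bins),
normalized as log2 of the sum over its chromosome-wide mean — the
methods literature describes the diamond sum but not the normalization,
and the log-ratio-to-mean convention makes profiles comparable across
matrices. Boundaries are local minima with topographic prominence ≥ 0.2
(log2 units); "low sums" is unquantified in the source literature, so
the prominence threshold is exposed. Virtual 4C is the balanced
viewpoint row (optionally mean-smoothed, self-bin flagged); the loop
pileup averages (2·flank+1)² O/E windows at anchor pairs elementwise and
scores central enrichment as the centre pixel over the mean of the four
flank/2-sized corner quadrants.

## TF networks and differential accessibility

Motif scanning and super-enhancer assignment are out of scope: the edge
list is the module boundary. TF strength is out-degree minus in-degree
over unique directed edges (self-loops dropped; parallel edges collapse
by default, with a multiplicity-weighted option since motif-count
weighting is ambiguous in the source material). Strengths sum to zero
over any network — each edge contributes +1 and −1 — which the tests use
as a conservation oracle. Ranking ties break alphabetically. Network
comparison reports the shared-TF fraction over the node union, per-TF
strength deltas, and an OLS fit with 95% confidence intervals, refused
below 3 shared TFs.

Gene activity sums counts in bins overlapping ±5 kb of each TSS (with
flank 0 meaning the single TSS-containing bin); optional k-NN smoothing
on top principal components is off by default. Metagene scores are
means of per-gene z-scored CPM activities over each marker set —
z-scoring after CPM keeps labels invariant to per-cell depth and stops
high-activity genes from dominating an unweighted aggregate. Ties and
zero-depth cells are left unlabeled with a flag.

Differential accessibility realizes "two-sided t test with BH
correction" concretely as a Welch t-test on log1p CPM per feature
(variance model unstated in the source; unequal variances are the safe
default), BH across tested features via `p.adjust`, and log2 fold
change of mean CPM with pseudocount 1. Defaults flag features with
adjusted p ≤ 0.001 and |logFC| ≥ 1.5; both are arguments because the
fold-change base and pseudocount behind published thresholds are not
fully specified.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions. One 2-Mb chromosome carries a 13-gene cluster (TSSs every
12 kb — on 2-kb bin edges, so planted transitions are bin-aligned — for
a ~156-kb span) and 20 background marker genes per cell type. The
fixture tiles the cluster ± 50-kb flanks with six segments whose
(ATAC, H3K27ac, H3K27me3) expected fragments/cell/2-kb-bin are

| segment | span | ATAC | H3K27ac | H3K27me3 |
|---|---|---|---|---|
| s0 | upstream flank | 0.05 | 0.05 | 0.10 |
| s1 | genes 1–4 | 0.60 | 0.60 | 0.25 |
| s2 | genes 5–6 | 0.40 | 0.40 | 0.40 |
| s3 | genes 7–9 | 0.40 | 0.40 | 0.70 |
| s4 | genes 10–13 | 0.05 | 0.05 | 1.20 |
| s5 | downstream flank | 0.05 | 0.20 | 0.30 |

The magnitudes are free parameters chosen once to realize the ordinal
structure the analysis targets — three 3-modality transitions, one
2-modality transition (5′ decay of the repressive signature, ATAC
unchanged), one 1-modality transition (H3K27me3-only step at gene 7) —
not measured values. Counts are Poisson by default (the minimal
assumption; negative binomial with dispersion 0.3 is an option),
fragment lengths mix subnucleosomal (~80 bp) and mononucleosomal
(~200 bp) modes, and a configurable fraction of cells (default 0.4,
"group 2") has its 3′ H3K27me3 rates depleted to the flank level while
H3K27ac is generated identically in both groups — making H3K27ac
exchangeable across groups by construction, which calibrates the
uniformity test. Everything is seeded: a fixed seed gives byte-identical
fragment files.

Cell-type fragment sets enrich each type's own marker promoters in ATAC
and H3K27ac and mark them repressive in the other types; 50 background
bins are planted as differentially accessible between two regions of the
first cell type. Contact matrices follow `depth/(1+d)` distance decay
with 2× within-TAD enrichment and 3× planted loop pixels plus Poisson
noise; `split_tad` places the internal junction at the fixture's
primed-to-silenced border, `single_tad` wraps the whole cluster. TF
edge lists are sampled with per-TF out-propensities and recorded truth
degrees.

What the generator does **not** emulate: mappability and GC structure,
peak-shaped signal within segments (rates are piecewise constant),
barcode errors and doublets, read-level sequence, modality-specific
background (cross-mark contamination), and contact-matrix artefacts
such as unmappable bins in the middle of domains. Passing tests
therefore demonstrate algorithmic correctness and statistical
calibration under the stated generative model, not robustness to every
artefact of real single-cell chromatin data.

## Problem sizes and determinism

Tests and the acceptance script use the sizes at which the statistical
claims are made: 500 cells per modality for fixture recovery (20 seeds
for stability), 300+300 cells for differential calibration on planted
8-fold effects, 500 null fixtures (499 permutations each) for the
type-I error of the permutation test, and ≤ 60-bin matrices for the
brute-force equivalence oracles (which must agree to 1e-9 relative).
All randomness flows from explicit seeds; generators reset the RNG from
`config$seed`, so any stage can be reproduced in isolation.

## Known limitations

- The border detector assumes approximately piecewise-constant signal
  with transitions sparser than the smoothing scale; ramps spread over
  many bins yield single boundaries at the steepest point.
- Grades count modalities only; amplitude is reported but does not
  enter the grade, so a barely-threshold three-modality border outranks
  a massive single-modality one.
- The domain rule depends on a sensible baseline interval; a baseline
  overlapping true signal compresses folds toward 1. (The fixture uses
  the upstream flank, as the field does.)
- Insulation boundaries near the matrix edge (within one window) are
  undefined by construction; junctions closer than the window to a
  masked region cannot be called.
- The 2-means split is one-dimensional by design; bimodality in a joint
  (H3K27ac, H3K27me3) space would need the multivariate extension.
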