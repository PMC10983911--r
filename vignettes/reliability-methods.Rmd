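---
title: "Methods: reliability of repeated-measures brain maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability of repeated-measures brain maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxrel)
```

## The measurement model

The unit of analysis is an `n × k` data matrix per voxel (or per ROI-mean
series): `n` subjects, each contributing one statistic on each of `k ≥ 2`
measurement occasions — runs within a session or sessions months apart. The
two-way crossed ANOVA with subjects random and occasions fixed decomposes
the total sum of squares into subject, occasion and residual components:

- `MSBS = SS_subjects / (n−1)` — between-subject mean square,
- `MSC  = SS_occasions / (k−1)` — occasion (column) mean square,
- `MSE  = SS_residual / ((n−1)(k−1))` — two-way residual,
- `MSWS = (SS_total − SS_subjects) / (n(k−1))` — one-way pooled
  within-subject mean square.

Three single-measurement ICC estimands follow. Consistency, ICC(3,1),
treats occasions as fixed and ignores occasion mean shifts — the right
choice when runs are administered in a fixed order and later sessions carry
practice effects, so occasion effects are structural rather than
exchangeable. Agreement, ICC(2,1), additionally charges occasion variance
to the denominator. ICC(1) pools all within-subject variation. The package
defaults to `icc_3` everywhere; `icc_2` and `icc_1` are first-class options.

Confidence bounds come from F pivots: `F = MSBS/MSE` on `(n−1, (n−1)(k−1))`
degrees of freedom for consistency, `F = MSBS/MSWS` on `(n−1, n(k−1))` for
the one-way form. For agreement no exact pivot exists; we use the
Shrout–Fleiss interval with Satterthwaite degrees of freedom, the same
construction used by the established ICC routines in the Python `pingouin`
library, against which our implementation is cross-checked in the test
suite. These F-based intervals are analytic and cheap, which matters when
they are computed for every voxel.

### Numerical choices

- Degenerate zero-variance units (a voxel constant across all subjects and
  occasions) return `NaN`, not 0: "no signal" is distinct from "no
  consistency", and `NaN` voxels are excluded from in-mask medians
  downstream.
- Negative ICC estimates are reported as computed, never floored at zero —
  empirical medians of weak contrasts are legitimately slightly negative.
- Tiny negative sums of squares from floating-point cancellation are
  clamped to zero before forming mean squares.
- The voxelwise engine is a single vectorised code path over `n × V`
  matrices; the test suite verifies it is numerically identical (1e−8) to a
  per-voxel `aov()`-based oracle, including bounds.

## Volumes, grids and masks

All volumes participating in one analysis must share a grid: identical
array dimensions and affines equal within 1e−4 mm. Mismatches are an error;
the package never resamples silently, because inputs to a reliability
analysis are expected to be in one common (MNI-like) space already. Voxel
flattening uses R's native column-major array order over the nonzero mask
voxels — a deterministic, pure function of the mask.

A reference map (e.g. a meta-analytic z-map) partitions the analysis mask
at a threshold (conventionally z = 3.1, i.e. uncorrected p ≈ .001) into
*suprathreshold* task-positive voxels (strictly `>`) and *subthreshold*
voxels (strictly `<`). A voxel exactly at the threshold belongs to neither:
"exceeds" is read strictly, and the case has measure zero for real-valued
maps.

## Group-map similarity

Thresholded binary maps compare by Jaccard `|A∩B|/|A∪B|` or Dice
`2|A∩B|/(|A|+|B|)`; continuous maps by Spearman rank correlation within a
mask. Ties are handled by average ranks (the textbook `1 − 6Σd²/(n(n²−1))`
formula is the tie-free special case) — ties are common in masked,
quantised statistical maps, so the tie-naïve formula is not used directly.
When both binarized maps are empty the similarity is `NaN` rather than 0 or
1: an empty-vs-empty comparison is vacuous and should fail loudly in
downstream aggregation, not masquerade as perfect (or zero) overlap.

Group t-maps are converted to Cohen's `d = t/√N` before thresholding when
maps computed at different sample sizes must share a threshold; the
conversion is monotone and sign-preserving, so thresholding `d` at `x` is
identical to thresholding `t` at `x√N`.

## Fixed-effects combination and design efficiency

Run-level effect estimates combine into session-level estimates by
inverse-variance weighting: `β_fx = Σ(βᵢ/σᵢ²)/Σ(1/σᵢ²)`,
`σ²_fx = 1/Σ(1/σᵢ²)`, computed voxelwise on maps so that session-level
stacks feed the voxelwise ICC exactly like run-level stacks. Contrast
efficiency `1/(c(X'X)⁻¹c')` is reported per (design, contrast) pair;
comparing parameterizations is a reporting concern, not a separate
computation.

## The multiverse layer

A decision grid spans four categories — smoothing FWHM, motion correction,
model parameterization, contrast. The default realized grid is 5 kernels ×
4 motion options × 3 parameterizations × 4 contrasts = 240 permutations;
the proposed variant with two additional high-motion-exclusion options
gives 360. Smoothing kernels derive from acquisition voxel size as
`multiplier × voxel × weight` (multipliers 1.5–3.5 by 0.5), rounded to one
decimal; a weight of 0.5 accommodates acquisitions whose large voxels carry
more inherent smoothness (4 mm voxels → 3.0–7.0 mm kernels, versus 3.6–8.4
mm for 2.4 mm voxels).

Enumeration order is fixed (FWHM outermost, contrast innermost, ids 1..R)
so tables are byte-reproducible. The package does not run GLMs: it consumes
per-permutation summary estimates (or ICC maps) keyed by permutation id.
`collect_estimates()` pools across samples by the mean and attaches a
`mean ± 1.96·SE` across-sample interval — the interval construction for
spec-curve panels is a documented package choice, since only "95%
confidence interval (across samples)" is conventional. Rows rank ascending
by estimate with ties broken by permutation id; percentile selection is
nearest-rank (`ceiling(p·R)`), so the 25th percentile of 240 rows is rank
60. Missing permutations are an error, never silently dropped.

## Bootstrap stability across sample size

`bootstrap_stability()` draws subjects with replacement at each grid size
(default 25 to 525 by 50, 100 iterations per size), recomputes the
voxelwise ICC on each subsample and retains the in-mask medians of the ICC,
MSBS and MSWS maps. Per-size summaries use percentile (2.5/97.5) intervals
across iterations rather than normal theory — more honest at 100 draws. A
master seed spawns one substream per (size, iteration), making the grid
reproducible and order-independent. Draws are with replacement by design;
a without-replacement option exists so that a single full-sample draw
reproduces the full-data analysis exactly (an identity the tests exploit).
The bootstrap resamples precomputed subject maps; it does not re-run any
upstream model fitting.

## What the synthetic generator emulates — and what it does not

`simulate_stack()` draws voxel values as `y_ijv = μ + shift_j + b_iv +
e_ijv` with `b ~ N(0, σ_b²)`, `e ~ N(0, σ_e²)`, independent across voxels,
so every voxel has analytic ground-truth consistency `σ_b²/(σ_b²+σ_e²)`. A
spherical "task-positive" region carries its own variance pair, emulating
the elevated reliability of strongly activated cortex; the matching
synthetic reference map exceeds z = 3.1 exactly on that sphere and the
synthetic atlas labels it 1 (complement 2).

Defaults model a small test–retest study: 60 subjects, two occasions,
background ground truth 0.2 (σ_b² = 0.25, σ_e² = 1 — the "poor" range
typical of single-contrast task fMRI) and target-region truth 0.5 (σ_b² =
σ_e² = 1, the upper range reported for strongly activated regions). The
occasion shift is additive and deterministic, so consistency is invariant
to it by construction while agreement degrades — a property the tests
assert exactly, not approximately.

What is deliberately *not* emulated: spatial autocorrelation (no smoothing
is replayed — ground truth stays analytic), BOLD timeseries, HRFs, motion
artifacts, and any dependence between the decision-grid labels and the
simulated maps. Passing tests therefore demonstrate the estimators and
orchestration are correct, not that any particular real dataset is
reliable; decision-grid effects on real data cannot be reproduced from
simulations that do not model the decisions' physical consequences.

Problem sizes in the test suite are chosen for tight Monte-Carlo behaviour
at interactive runtimes: parameter recovery uses 5³–6³ voxel volumes with
n = 200 over 20 seeds; the stability check uses a 10³ volume with n = 525
across the full default grid. These sizes put the binomial/Monte-Carlo
noise well inside the asserted tolerances.

## Open design points, resolved

- **ROI reliability**: the ROI-mean-series-then-ICC reading is the default
  (it matches the common atlas workflow); median-of-voxelwise-ICCs is
  exposed as `strategy = "voxelwise_median"` since both readings are
  defensible and they answer different questions (reliability of the
  aggregate signal vs typical voxel reliability).
- **Exact-threshold voxels** in reference partitions belong to neither
  side, per the strict reading of "exceed".
- **Voxel ordering** is column-major (R's native order) rather than the
  C-order convention of array libraries in other languages; any fixed order
  serves determinism equally, and this one avoids a transpose on every
  access.
- **CLI errors** exit nonzero with a single-line diagnostic; all
  subcommands are thin wrappers over exported functions and are tested
  in-process.

## Known limitations

Average-measure ICC variants (ICC(·,k)), multivariate reliability indices
(I2C2, discriminability), bootstrap/Bayesian ICC intervals, cluster-extent
or corrected-map thresholding, and hierarchical models over spec-curve
estimates are out of scope; the spec-curve writer emits tidy long-format
tables suitable for any external mixed-model tool. Grids must match
exactly — there is no resampling. Surface formats (GIFTI/CIFTI) are not
read.
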