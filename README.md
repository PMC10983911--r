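# voxrel

Test–retest reliability of repeated-measures 3D statistical brain maps.

## The problem

Task fMRI studies routinely ask whether a contrast map measured today would
look the same if measured again — across runs within a session, or across
sessions months apart. Two different questions hide under "reliability":

- **Individual-level consistency**: does a voxel's (or region's) effect
  estimate rank subjects the same way on both occasions? This is an
  intraclass correlation (ICC) question, answered per voxel or per ROI.
- **Group-level similarity**: does the thresholded group activation map
  select the same voxels on both occasions (Jaccard/Dice), and do the
  unthresholded group maps agree in their spatial ordering (Spearman)?

Both answers depend on upstream analytic decisions — smoothing kernel,
motion-correction strategy, task-model parameterization, contrast choice —
so `voxrel` also orchestrates *multiverse* analyses over a decision grid,
summarises them as specification curves, and charts how estimates stabilize
with sample size via bootstrap subsampling.

Everything runs end-to-end on synthetic data with analytically known ground
truth, so the machinery is testable without any imaging downloads.

## The statistics

For `n` subjects measured on `k` occasions, the two-way crossed ANOVA
(subjects random, occasions fixed) yields mean squares MSBS
(between-subject), MSC (occasion), MSE (residual), and the one-way pooled
within-subject MSWS. The single-measurement ICC family is

    ICC(3,1) = (MSBS − MSE) / (MSBS + (k−1) MSE)               consistency
    ICC(2,1) = (MSBS − MSE) / (MSBS + (k−1) MSE + k(MSC − MSE)/n)  agreement
    ICC(1)   = (MSBS − MSWS) / (MSBS + (k−1) MSWS)             one-way

with confidence bounds from the F statistic (`MSBS/MSE` or `MSBS/MSWS`;
Shrout–Fleiss interval for agreement). Group similarity uses
`J(A,B) = |A∩B| / |A∪B|`, `Dice = 2|A∩B| / (|A|+|B|)` on binarized maps and
Spearman rank correlation on continuous maps; t-maps convert to Cohen's
`d = t/√N` so thresholds are comparable across sample sizes. Design
efficiency is `1 / (c (X'X)⁻¹ c')` and run-level estimates combine by
precision-weighted fixed effects.

## Worked example

The classic scaling trap: occasion B is exactly 3× occasion A, so Pearson
correlation is perfect while consistency is not.

```r
library(voxrel)
a <- c(1, 3, 6, 9, 12)
b <- 3 * a
icc_scalar(cbind(a, b), icc_type = "icc_3")
#> <icc_fit> icc_3 = 0.6000 [-0.4120, 0.9493] (alpha = 0.05, n = 5, k = 2)
cor(a, b)
#> [1] 1
```

The ICC of 0.60 (not 1.0) reflects that tripling every score changes the
within-subject agreement even though the subject ordering is intact; the
wide interval is what five subjects buy you. `glance()` exposes the
underlying mean squares (MSBS 157.6, MSWS 108.4, MSC 384.4, MSE 39.4).

A full voxelwise run on synthetic data with a planted "task-positive"
sphere of elevated between-subject variance:

```r
sim  <- simulate_stack(sim_config(seed = 42))      # 60 subjects, 2 occasions
refs <- make_reference_and_atlas(sim_config(seed = 42))
maps <- voxelwise_icc(sim$stack, sim$mask, icc_type = "icc_3")
maps
#> <reliability_maps> icc_3, n = 60, k = 2, grid 10 x 10 x 10
#>   median in-mask ICC = 0.2234

parts <- partition_by_reference(refs$reference, sim$mask, threshold = 3.1)
median_within_mask(maps$icc, parts$supra)   # 0.518  (truth 0.5 inside sphere)
median_within_mask(maps$icc, parts$sub)     # 0.199  (truth 0.2 outside)

roi_icc(sim$stack, refs$atlas)
#> # A tibble: 2 × 8
#>   roi_label roi_name estimate  lower upper    msbs    msws voxel_count
#>       <int> <chr>       <dbl>  <dbl> <dbl>   <dbl>   <dbl>       <int>
#> 1         1 roi-1       0.387  0.149 0.582 0.0213  0.00928         123
#> 2         2 roi-2       0.124 -0.132 0.365 0.00144 0.00111         877
```

The suprathreshold median recovers the planted ground truth (0.5 vs 0.2);
the ROI-mean-series ICC for the target region sits below the voxelwise
truth because spatial averaging shrinks between-subject variance along with
noise. `autoplot()` works on reliability maps, spec-curve tables and
stability curves; `tidy()`/`glance()` return tibbles throughout.

A command-line surface wraps the same functions:

```sh
Rscript inst/scripts/voxrel.R simulate --out fix --n-subjects 60 --seed 1
Rscript inst/scripts/voxrel.R icc --manifest fix/manifest.tsv \
    --mask fix/mask.nii.gz --reference fix/reference.nii.gz --out out/
```

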