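# adchist

Fast estimation of age-appropriate brain volume from routine
diffusion-weighted MRI.

Brain atrophy — loss of brain tissue with enlargement of the cerebrospinal
fluid (CSF) spaces — occurs in many diseases but also in normal aging, and
deciding whether an observed volume loss is still age-appropriate is a
recurring question in neuroradiology. Voxel-based morphometry can answer it
but needs dedicated high-resolution 3-D acquisitions, segmentation and
spatial normalization. `adchist` implements a much lighter alternative that
works on a sequence acquired in almost every clinical brain exam: the
diffusion-weighted (DWI) pair of a b0 image and a dw image at
b = 1000 s/mm².

## Method

For every voxel above a combined noise/skull threshold the apparent
diffusion coefficient is computed from the two-point signal relation

&nbsp;&nbsp;&nbsp;&nbsp;ADC = ln(S_b0 / S_dw) / b  (mm²/s)

Brain tissue forms a clear peak in the ADC histogram near
0.75 × 10⁻³ mm²/s, while CSF (free water, ADC ≈ 3 × 10⁻³ mm²/s) and
tissue/CSF partial-volume voxels form a high-ADC tail. The pipeline:

1. **Self-calibration** — MR intensities have no absolute scale, so both
   volumes are rescaled to map the mode of the dw intensity histogram to
   250. All thresholds operate in these calibrated units.
2. **Masking** — voxels with b0 ≤ 50 or dw ≤ 1 (calibrated units) are
   excluded: background and skull are dark in b0, while CSF stays bright
   there and is retained.
3. **ADC histogram** — per-subject histograms (bin width 0.02 × 10⁻³ over
   [0, 4 × 10⁻³] mm²/s) are expressed in percent of the masked voxel
   count, which normalizes away head size.
4. **Characteristic value** — on the cohort-average histogram the tissue
   peak and its left 1%-of-maximum basis are located; mirroring the basis
   about the peak gives the characteristic ADC `a_char` separating
   tissue-dominated from CSF-dominated voxels
   (`a_char − peak = peak − basis`).
5. **Brain fraction** — each subject's statistic is the percentage of
   masked voxels with ADC ≤ `a_char`.
6. **Cohort statistics** — age-group means with pooled-variance t-tests
   (Bonferroni-corrected), and a quadratic age trajectory
   y = c₀ + c₁·x + c₂·x², whose derivative c₁ + 2·c₂·x is the
   tissue-loss rate in %/year.

Because no public dataset accompanies the method, the package ships a
synthetic DWI head-phantom generator (`phantom_config()`,
`sample_cohort()`, `synthesize_volumes()`) with known ground-truth
tissue/CSF composition, Rician noise, partial volume and arbitrary
per-subject intensity scaling, so the whole pipeline is testable end to
end.

## Worked example

```r
library(adchist)

cfg      <- phantom_config()                 # 224 x 224 x 30 DWI phantom
traj     <- age_trajectory(83.5, -0.068, -0.0027, subject_sd = 1.5)
manifest <- sample_cohort(24, c(5, 85), traj, seed = 7,
                          scale_range = c(0.2, 5))
pairs <- lapply(seq_len(nrow(manifest)), function(i)
  synthesize_volumes(manifest[i, ], cfg, fast = TRUE))
names(pairs) <- manifest$subject_id

analysis <- analyze_cohort(manifest, pairs = pairs)
analysis
#> <adc_cohort_analysis> 24 subjects
#> <characteristic_value> peak 0.750, basis 0.330 -> a_char 1.170 (x1e-3 mm2/s, 1% level)
#> <adc_quadfit> [all, n=24] y = 85.98 -0.09045 x -0.0020852 x^2 (rmse 0.922%)
#>   slope: -0.174 (age 20), -0.299 (age 50), -0.424 (age 80) %/year
#> <adc_quadfit> [female, n=13] y = 86.39 -0.1129 x -0.0018272 x^2 (rmse 0.764%)
#>   slope: -0.186 (age 20), -0.296 (age 50), -0.405 (age 80) %/year
#> <adc_quadfit> [male, n=11] y = 85.13 -0.05014 x -0.0024937 x^2 (rmse 1.03%)
#>   slope: -0.150 (age 20), -0.300 (age 50), -0.449 (age 80) %/year
```

The characteristic value lands at 1.17 × 10⁻³ mm²/s: the tissue peak of
the cohort-average histogram sits at 0.75 × 10⁻³, its left 1%-basis at
0.33 × 10⁻³, and the mirror rule puts the partition point at
0.75 + (0.75 − 0.33). Each subject's brain fraction is the histogram mass
below that value; the quadratic fit then recovers a trajectory close to
the generating one (c₀ = 83.5, c₁ = −0.068, c₂ = −0.0027) despite the
24-subject cohort, the random per-subject intensity scales and the noise.

Per-subject results are a tibble, and fits have broom-style accessors:

```r
head(analysis$results, 3)
#>   subject_id   age sex    brain_fraction scale_factor dw_mode mask_count
#> 1 S0001       84.1 male             64.2        1.61    156.       84000
#> 2 S0002       36.8 female           80.4        2.91     86.0      84000
#> 3 S0003       14.3 male             85.7        0.631   396.       84000

analysis$group_summary
#>   group lower upper     n  mean    sd
#> 1     1     0    20     7  84.7  1.09
#> 2     2    20    40     6  80.9  1.02
#> 3     3    40    60     4  77.4  2.45
#> 4     4    60    90     7  66.0  3.35

glance(analysis$fits$all)       # coefficients, rmse, slopes at 20/50/80
tidy(analysis$fits$all)         # per-coefficient estimates and SEs
autoplot(analysis$average_histogram)
plot_age_trajectory(analysis$results, analysis$fits)
```

File-based workflows use `write_phantom_cohort()` / `read_manifest()` /
`analyze_cohort(manifest)` with NIfTI volumes (two 3-D files or one 4-D
file per subject), and `write_cohort_report()` emits JSON/CSV/TSV reports
embedding the full configuration and its hash. A command-line front end
(`inst/scripts/adchist`) exposes `simulate`, `analyze`, `cohort` and
`fit` subcommands.

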