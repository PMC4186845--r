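# boldvar

Relating resting-state fMRI activity to behavioural performance across
subjects. `boldvar` is an R implementation of a classic individual-differences
resting-state analysis: per-subject preprocessing of 4D BOLD time series,
voxelwise **BOLD signal variability** mapping, **seed-based functional
connectivity** with the Fisher z-transformation, across-subject correlation of
either metric with a behavioural score, and **Monte-Carlo cluster-extent
correction** of the resulting statistical maps. It is aimed at researchers who
want a small, fully scriptable, fully testable version of this pipeline — the
package ships a seeded synthetic-cohort generator so every stage runs and is
validated end to end without any imaging data download.

## The method

For each subject, each resting-state run is processed as: spatial smoothing
(Gaussian, 3 mm FWHM) → discard of the first 5 frames → nuisance regression →
percent-signal-change conversion → concatenation of runs. The nuisance model
has 19 regressors: mean, linear and quadratic trends; six rigid-body motion
parameters and their first derivatives; and mean white-matter and CSF signals
(from partial-volume maps thresholded at 0.99 and eroded by 2 voxels) and
their first derivatives. After ordinary-least-squares removal of these terms
the temporal mean is restored, and each voxel becomes a percent-change series

    pc(t) = 100 * (y(t) - mean(y)) / mean(y).

Two per-subject metrics are computed inside the analysis mask:

* **variability** — the temporal standard deviation of `pc`, per voxel;
* **connectivity** — Pearson correlation of each voxel's `pc` with the mean
  `pc` of a seed parcel, Fisher-transformed, `z = atanh(r)`.

Across subjects, each metric is correlated with a behavioural score at every
voxel; the two-tailed p-value comes from `t = r sqrt((n-2)/(1-r^2))` with
`n - 2` degrees of freedom. Multiple comparisons are handled by cluster
extent: white Gaussian noise fields are smoothed to the analysis smoothness,
standardised within the mask, thresholded two-sided at the voxelwise p, and
the largest suprathreshold connected component is recorded over (by default)
1000 iterations; the minimum cluster size `k_min` controlling familywise
error at alpha is the smallest extent reached in at most a fraction alpha of
null fields. Surviving clusters are reported with an anatomical label, a
hemisphere, and peak coordinates in LPS orientation.

Head motion is summarised per subject by Power-style framewise displacement
(sum of absolute frame-to-frame translation differences plus rotations
converted to mm on a 50 mm sphere), and its mean is tested against the score
as a confound check.

## Worked example

Generate a synthetic ten-subject cohort with a variability-score effect in
the left caudate parcel (target across-subject r = 0.9) and a left-caudate →
right-fusiform connectivity coupling that strengthens with the score, then
run the variability analysis end to end:

```r
library(boldvar)

cfg <- cohort_config(n_subjects = 10, grid_shape = c(24, 24, 20), n_runs = 1,
                     n_timepoints_per_run = 120, seed = 42)
coh <- generate_cohort(cfg)
coh
#> <bold_cohort> 10 subjects, grid 24x24x20 at 2 mm, 1 run(s) x 120 frames (TR 2 s)
#>   scores 80.9-95.4, 8 parcels

res <- run_variability_analysis(
  run_config(out_dir = "demo", n_iter = 500, seed = 42), cohort = coh)
res$k_min
#> [1] 16
format_cluster_report(res$report)
#> # A tibble: 2 × 10
#>   cluster_id region   side  n_voxels peak_x peak_y peak_z peak_r    peak_p  sign
#>        <int> <chr>    <chr>    <int>  <dbl>  <dbl>  <dbl>  <dbl>     <dbl> <dbl>
#> 1          1 fusiform R           88     -9      7      7   0.98 0.0000005     1
#> 2          2 caudate  L           64     11      5     -5   0.86 0.002         1
res$motion_confound
#> # A tibble: 1 × 5
#>       r     p     t    df     n
#>   <dbl> <dbl> <dbl> <dbl> <int>
#> 1 0.241 0.503 0.702     8    10
```

Reading the output: the Monte-Carlo null for this mask and smoothness says
clusters of at least 16 voxels control familywise error at 0.05. Two clusters
survive. The left caudate cluster (64 voxels, peak r = 0.86, p = 0.002 at
n = 10) recovers the injected variability effect. The right fusiform cluster
is the connectivity coupling showing through variability: its amplitude grows
with the score, which raises that parcel's signal SD too. Peak coordinates
are in mm, LPS orientation (left hemisphere prints positive x). The motion
confound check shows mean framewise displacement is unrelated to the score
(r = 0.24, p = 0.50), so motion does not explain the brain-score
correlations.

Connectivity runs the same way:

```r
seeds <- seed_definitions(coh$labels, coh$parcellation)
conn <- run_connectivity_analysis(
  run_config(out_dir = "demo_conn", n_iter = 500, seed = 42),
  cohort = coh, seeds = seeds[seeds$label == 1, ])
```

Result objects have `tidy()`, `glance()` and `autoplot()` methods; a thin
command-line front end with `simulate`, `variability`, `connectivity` and
`cluster-null` subcommands is installed at `inst/cli/boldvar`.

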