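---
title: "Methods: BOLD variability, seed connectivity and cluster-extent inference in boldvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BOLD variability, seed connectivity and cluster-extent inference in boldvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`boldvar` estimates, for every brain voxel, how strongly a resting-state fMRI
metric covaries with a behavioural score across subjects, and decides which
regions of that map survive multiple-comparison correction. This vignette
documents the model, the parameters that matter, the synthetic data the
package validates itself on, and the numerical and design choices made where
more than one defensible option existed.

## The statistical model

Let `y_v(t)` be the BOLD signal of voxel `v` after spatial smoothing,
steady-state frame discard and nuisance regression (with the temporal mean
restored). The percent-change series is `pc_v(t) = 100 (y_v(t) − ȳ_v)/ȳ_v`,
computed per run and concatenated.

Two per-subject summaries are formed:

* **Variability**: `SD_v = sd_t(pc_v)`, in percent units. This treats the
  amplitude of spontaneous fluctuations as the quantity of interest, not
  their phase or topology.
* **Connectivity**: for a seed parcel `S`, `r_v = cor_t(pc_v, mean_{w∈S}
  pc_w)` and `z_v = atanh(r_v)`. The Fisher transform stabilises the
  sampling variance so across-subject comparison of correlations is
  legitimate.

Across `n` subjects the metric at each voxel is correlated with the score by
Pearson's r, with the two-tailed p from `t = r√((n−2)/(1−r²))` on `n−2`
degrees of freedom — identical to the slope test of the simple linear
regression of the metric on the score, which is how such brain–behaviour
analyses are usually described. With the package's reference cohort size of
`n = 10`, the voxelwise two-tailed p < 0.05 criterion corresponds to
`|r| > 0.632`; reported peak correlations in this regime are therefore
necessarily large, and their magnitudes should be read with that selection
effect in mind.

### Assumptions

* Subjects' images are already on a common grid (the generator produces
  aligned data; registration is out of scope).
* Scores and metrics are related monotonically enough that Pearson
  correlation is meaningful; no robust or rank-based variant is offered.
* Voxelwise tests are two-tailed. The direction of reported effects is
  carried by the sign of r and clusters are sign-homogeneous by default.

## Cluster-extent correction

Voxelwise thresholding at p < 0.05 over tens of thousands of voxels needs a
familywise correction. The package uses the Monte-Carlo ("AlphaSim-style")
approach: simulate smooth Gaussian null fields on the analysis mask, apply
the same two-sided voxel threshold, record the largest suprathreshold
connected component per iteration, and read off the minimum extent `k_min`
reached by at most a fraction `alpha` of iterations. Observed clusters of at
least `k_min` voxels are reported.

Numerical details, all configurable and logged in the provenance file:

* **Null field**: white Gaussian noise on the full grid, smoothed with the
  separable Gaussian kernel, then standardised to mean 0 / SD 1 *within the
  mask*. Smoothing before masking keeps the field stationary at the mask
  border.
* **Cluster-forming threshold** (`voxel_p`, default 0.05 two-sided): the
  literature this pipeline descends from states only the corrected level
  and the resulting extent, so the forming threshold is an explicit,
  required configuration value rather than a hidden constant.
* **Connectivity rule**: faces-touch (6-connectivity) by default, matching
  the first-nearest-neighbour convention of the reference implementation;
  18 and 26 are selectable.
* **Null smoothness** (`null_fwhm`, default = the applied smoothing FWHM,
  3 mm): residual-smoothness estimation is deliberately out of scope. For
  variability maps this default is not just convenient but correct for the
  synthetic data: the generator smooths noise at 3 mm and preprocessing
  smooths again (combined ≈ 4.2 mm), but an SD map of a Gaussian field
  inherits the *squared* field correlation, which corresponds to a kernel
  narrower by √2 — landing back at ≈ 3 mm. For connectivity z-maps the
  correlation is approximately linear in the field, so their smoothness is
  the full ≈ 4.2 mm and the 3 mm default is anti-conservative; see
  Limitations.
* **Sign splitting**: positive and negative clusters are extracted
  separately (default), since effects are reported signed. Under a smooth
  null, opposite-sign suprathreshold voxels are essentially never
  face-adjacent, so this does not change the familywise error in practice.

The familywise calibration is verified empirically in the test suite: with a
40×40×40 mask, 3 mm FWHM at 2 mm voxels and voxel p = 0.05, `k_min` from a
1000-iteration null applied to 1000 fresh null fields yields a surviving
cluster in 5% ± 2% of fields.

## Reporting

Clusters are reported one row per cluster: parcellation label at the peak
voxel (maximum |r|; ties broken deterministically by the smallest linear
index), hemisphere from the sign of the left–right world coordinate, peak
coordinates in mm, and peak r and p. Coordinates default to **LPS**
orientation (x grows to the subject's left), the convention of the
anatomical tables this report format mirrors; RAS is available. A
`composition` column counts voxels per parcel inside each cluster, since a
single cluster can straddle parcels. `format_cluster_report()` rounds the
way such tables are printed (r to 2 decimals, p to 1 significant figure).
Seed-interior voxels are retained in connectivity maps — they correlate
highly by construction — and it is the report consumer's choice to discount
clusters inside the seed.

## Preprocessing parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_discard` | 5 | frames | magnetisation steady state (10 s at TR 2 s) |
| `fwhm` | 3 | mm | light smoothing; preserves subcortical detail |
| `mask_erosion` | 2 | voxels | per-slice removal of brain-edge voxels |
| `pv_threshold` | 0.99 | fraction | near-pure WM/CSF for nuisance means |
| `erosions` (tissue) | 2 | voxels | guards against grey-matter partial voluming |
| `head_radius` | 50 | mm | standard sphere for rotation-to-mm conversion |
| `lowpass` | off | — | high-frequency BOLD carries signal; optional 0.08 Hz, order-4 zero-phase Butterworth |
| `voxel_p` | 0.05 | two-tailed p | cluster-forming threshold |
| `alpha` | 0.05 | FWER | corrected level |
| `n_iter` | 1000 | iterations | Monte-Carlo resolution of 1/1000 on the null |

Further conventions: first derivatives in the nuisance design are backward
differences with a leading zero (keeps length, no look-ahead); trend columns
are centred polynomials over `0:(T−1)` (recorded in the design metadata);
motion regressors enter trimmed to post-discard frames; rotations default to
degrees (the unit travels with the motion matrix); SD uses the population
formula (divide by T — at T = 470 the sample-formula difference is ~0.1%,
and the choice is recorded on the map object).

## Degenerate inputs and numerical guards

* Voxels whose temporal mean is within 1e-6 of zero cannot be expressed in
  percent change; they are dropped from the analysis mask and counted in the
  preprocessing log, rather than generating infinities.
* `|r|` is clipped to 1 − 1e-7 before `atanh`, so saturated correlations map
  to a large finite z.
* A rank-deficient nuisance design falls back to the pivoted QR
  least-squares fit with a warning; near-collinearity (condition number
  > 1e8 after standardising the non-intercept columns) is flagged when the
  design is built.
* If a WM/CSF region is empty at the requested erosion — possible on small
  grids — the erosion count is reduced until the region is nonempty, and the
  value actually used is recorded in the log. At the default grid scale the
  requested two erosions always survive.
* Across-subject correlation at voxels with zero variance (e.g. constant z)
  is undefined and returned as NA, never silently zero.

## The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth. It
emulates:

* **Temporal autocorrelation**: AR(1) noise (coefficient 0.4 by default) —
  the simplest model with a realistic lag-1 structure.
* **Spatial smoothness**: white noise Gaussian-smoothed at 3 mm and
  restandardised within the mask, so the null-field smoothness matches what
  the cluster-null simulator assumes.
* **Behavioural scores**: uniform on [76, 96] percent — the span observed in
  small cohorts of this design — so injected effect sizes are comparable to
  published ones.
* **Variability effects**: within a chosen parcel, the per-subject signal SD
  is `baseline × (1 + 0.3 (r·z_s + √(1−r²)·η_s))` with `z_s` the
  standardised score and `η_s` unit Gaussian jitter; by construction the
  population correlation between SD and score is the target `r`, and the
  jitter shrinks to zero as the target approaches ±1. Measured calibration:
  mean recovered r = 0.91 over 20 cohorts at target 0.9.
* **Connectivity effects**: one latent AR(1) time course added to the seed
  parcel at fixed amplitude (0.8% by default) and to the target parcel with
  amplitude `slope × (score − score_min)` percent. Note a side effect that
  real data would share: an amplitude that grows with the score also raises
  the target parcel's SD, so a connectivity coupling induces a secondary
  variability–score effect there.
* **Head motion**: a Gaussian random walk on the six rigid-body parameters
  (rotations in degrees), rescaled so the mean Power framewise displacement
  equals the per-subject target exactly (FD is positively homogeneous in
  the trace, so rescaling is exact). Targets are drawn uniformly from
  0.06–0.11 mm. Motion traces are *not* coupled to the images: motion is a
  confound covariate here, not an image artifact model.
* **Anatomy**: an ellipsoidal brain mask with concentric CSF/WM/GM
  compartments and four bilateral box parcels placed in the grey-matter rim
  (so parcel signal is not absorbed by the WM/CSF nuisance regressors). The
  default grid is 48×56×40 at 2 mm — a desk-scale stand-in for a
  standard-space 2 mm grid.

What the generator does **not** emulate: physiological (cardiac/respiratory)
noise, motion-induced image artifacts, multi-echo signal properties,
within-parcel effect heterogeneity (effects are parcel-homogeneous — nothing
in the emulated study design constrains sub-parcel structure), field
inhomogeneity, or between-subject anatomical variability. Passing tests on
synthetic cohorts therefore demonstrate the statistical machinery —
calibration, error control, recovery — not robustness to every artifact of
real acquisitions.

## Validation experiment scale

The package validates itself at sizes chosen to make ground truth
measurable with comfortable margins:

* Familywise calibration: 40×40×40 all-true mask, 1000 calibration + 1000
  test null fields.
* End-to-end recovery: cohorts of n = 10 subjects on a 24×24×20 grid at
  2 mm, one 120-frame run, one effect parcel at target r = 0.9, 20 effect
  and 20 null replicates, 500-iteration nulls per run. Measured: surviving
  clusters overlap the effect parcel at Dice ≥ 0.5 in 100% of effect
  replicates; effect-free cohorts produce no clusters in 100% of
  replicates (seed 1).
* Generator calibration and null false-positive rates: 16³–20³-scale grids,
  6–30 replicates as the property requires.

These sizes are the package's validation choices; all machinery runs
unchanged at the default full scale.

## Known limitations

* The connectivity path's cluster correction uses the 3 mm default null
  smoothness while synthetic z-maps are ≈ 4.2 mm smooth, making it
  anti-conservative there; set `null_fwhm` accordingly (or implement
  residual smoothness estimation, which is deliberately out of scope) when
  calibrated error control on connectivity maps matters.
* Pearson correlation across n = 10 subjects has wide sampling error; the
  pipeline reports peak statistics for qualitative assessment, and nothing
  here corrects for the winner's-curse inflation of peak |r|.
* The Monte-Carlo null assumes Gaussian, stationary, isotropically smooth
  fields; heavy-tailed or spatially heterogeneous noise violates it.
* `min_cluster_size` resolves alpha only to 1/`n_iter`; requesting smaller
  alpha warns.
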