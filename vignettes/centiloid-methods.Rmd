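---
title: "Methods: MRI-free Centiloid quantification, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRI-free Centiloid quantification, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centiloidr)
```

## The problem

Amyloid-PET burden is usually reported as a standardized uptake value ratio
(SUVR): mean tracer uptake in a cortical target region divided by mean
uptake in a reference region assumed free of specific binding. Because SUVR
depends on tracer, scanner, and processing pipeline, cross-study reporting
uses the Centiloid (CL) scale, a linear rescaling anchored so that young
amyloid-negative controls (YC) average 0 and typical Alzheimer's-disease
patients average 100.

The conventional route to the cortical and reference masks runs through an
MRI-based cortical parcellation. When only the CT of a PET/CT session is
available, a CT-derived parcellation can substitute for the MRI one — but
its SUVR scale differs slightly, so it must be calibrated onto a scale with
a published CL conversion. This package implements that workflow end to
end: mask construction and SUVR extraction from co-aligned label volumes,
the linear-map algebra that chains SUVR scales to CL, the Level-1
acceptance check for a local standard-pipeline replication, and the cohort
statistics used to judge whether a new pipeline is as good as the
established ones. A synthetic phantom generator stands in for patient data.

## SUVR extraction

The target value is a single pooled-voxel mean over the union of four
cortical lobar masks (frontal, cingulate, lateral parietal, lateral
temporal). Reading "mean uptake in the target cortical areas" as one mean
over one cortical mask is a choice: averaging the four lobar means instead
would weight small lobes up. Both are implemented
(`target_weighting = "pooled"` is the default, `"mean_of_means"` the
alternative); with the default phantom geometry (equal lobe volumes) the
two coincide.

Four reference constructions are supported:

* **WC** — whole cerebellum (gray + white).
* **CG** — cerebellar gray matter.
* **pons**.
* **composite** — the unweighted average of the whole-cerebellum,
  brainstem and eroded-subcortical-white-matter *means*: each region
  contributes 1/3 regardless of its volume. A pooled-voxel variant
  (`composite_pooled = TRUE`) exists for sensitivity analysis; the two
  demonstrably diverge whenever region volumes differ, and the unweighted
  mean-of-means is the default because that is the literal published
  construction.

The eroded white-matter mask is built by smoothing the binarized
white-matter mask with a Gaussian kernel of 8 mm FWHM in millimetre space
and keeping voxels whose smoothed value is at least 0.70; the 0.70 cut
only makes sense on a [0, 1]-smoothed binary image, which is why the "8
mm³ resolution" phrase of the source construction is implemented as an
8 mm-FWHM Gaussian. The comparison is inclusive (>=) so results are
bit-reproducible, and the output is intersected with the input mask so
erosion can only shrink. A mask too thin for the requested erosion raises
an error rather than returning an empty mask.

All smoothing is separable discrete Gaussian convolution with
`sigma = FWHM / (2 * sqrt(2 * log(2)))` converted to voxel units per axis,
kernel taps at integer offsets truncated at 4 sigma and normalised to unit
sum, and reflective boundary handling — the standard imaging convention.
Voxel coordinates are 0-based in the NIfTI affine convention; nearest-
neighbour label resampling goes through the affine composition and can
only preserve or lose label IDs, never invent them.

## Centiloid calibration

Every conversion is affine, represented as a `linear_map` with unit tags
so chains cannot be composed out of order. The published constants (anchor
means 1.012 and 2.077; tracer conversion 0.39/0.61; the SUVR-to-CL
equations per pipeline and reference) live in one provenance-annotated
table (`cl_constants()`); call sites use the named constructors.

* `anchor_cl_map()` builds `CL = 100 (s - yc) / (ad - yc)`; it sends the
  YC anchor to 0 and the AD anchor to 100 exactly, by construction.
* `fbb_to_pib_map()` is the florbetaben-to-PiB surrogate conversion
  `PiB = (FBB - 0.39) / 0.61`.
* `compose_maps()` folds chains; composing the tracer map with the anchor
  map reproduces the printed standard-pipeline equation
  (slope 153.93 ≈ printed 154.0, intercept −155.06 ≈ printed −155.1).

Cross-pipeline calibration is the one fitted model in the package, exposed
in the classic R modelling idiom: `cl_calibrate(suvr_fs ~ suvr_ct, data)`
fits ordinary least squares with the MRI-based SUVR as the response — the
direction in which the fitted map is then used (CT SUVR in, calculated FS
SUVR out, then the published FS equation to CL). OLS ignores error in the
predictor; a Deming fit (error ratio 1) is available via
`method = "deming"` for sensitivity, but OLS is the default because the
fitted map is consumed in exactly the regression direction. For a simple
straight-line fit the regression R² equals the squared Pearson
correlation, so the object reports both names of the same number.

`level1_acceptance()` encodes the standard local-pipeline replication
bounds: R² strictly greater than 0.98, slope in [0.98, 1.02] and intercept
in [−2, 2]. The slope/intercept bounds are inclusive and the R² bound
strict — the inclusivity had to be pinned somewhere, and this is the
literal reading of the printed criteria. `level1_from_csv()` accepts a
user-supplied table of published-vs-local CL values for an actual
replication; no reference dataset is bundled.

## Cohort statistics

The ADCI-vs-YC separation is measured by the pooled-SD effect size
`d = (mu_p - mu_n) / sqrt((Np sig_p^2 + Nn sig_n^2) / (Np + Nn - 2))`.
The formula's variances are population variances while reported group SDs
are sample SDs, so the default convention computes each `N sig^2` term as
`(N - 1) s^2` — the classic pooled-variance form. This convention
reproduces the published effect sizes from the published group summaries;
the face-value `N s^2` alternative is exposed via
`variance = "population"`. Confidence intervals are non-parametric
bootstrap percentile intervals (default 10,000 resamples, each group
resampled at its own size, fixed seed); BCa is deliberately not used
because nothing more than "non-parametric bootstrapping" is specified.
Degenerate zero-variance resamples are skipped and counted, not fatal.

Variance homogeneity uses the classic Levene test — a one-way ANOVA on
absolute deviations from the group *means* (the median-centred
Brown–Forsythe variant is an option, not the default, since "Levene's
test" unqualified denotes mean centring). Pairwise two-sided variance-ratio
F tests follow, Bonferroni-adjusted as `min(1, p * K)` over the requested
comparisons.

ROC analysis treats high CL as positive with the rule `score >= t`.
Candidate thresholds are midpoints between consecutive distinct scores
plus infinite sentinels — whether the original analyses used observed
values or midpoints is unknowable from the printed results, and midpoints
give cutoffs that do not coincide with any observed subject. AUC is the
trapezoid over (1 − specificity, sensitivity), which equals the
Mann–Whitney U statistic scaled by the product of class sizes (a property
the tests verify on hundreds of random instances). The optimal cutoff
maximises Youden's J = sensitivity + specificity − 1; among ties the
highest-specificity threshold wins, favouring fewer false positives in a
screening context.

## The synthetic cohort: what it does and does not emulate

`phantom_spec()` lays out nine non-overlapping axis-aligned blocks (the
four target lobes; cerebellar white and gray blocks whose union is the
whole cerebellum; pons and the rest of the brainstem; subcortical white
matter) on a 48³ grid of 2 mm voxels. `make_phantom()` paints nominal
uptakes, convolves with the point-spread Gaussian (4 mm FWHM default, the
post-reconstruction smoothing of the emulated scans) and adds i.i.d.
Gaussian noise. The uptake, noise and perturbation streams are seeded
independently, so changing one leaves the others bit-identical.

`cohort_spec()` draws each subject's true CL from its group's normal
distribution. The defaults are the study conditions: group sizes
(23, 76, 207), ADCI 85.15 / 27.91 and YC 0.99 / 3.57 CL on the
CT-whole-cerebellum scale. No amyloid-negative CL distribution is
published, so the generator uses mean 5 / SD 10 CL — comfortably
sub-threshold, as visually negative patients are. The drawn CL maps back
to a target-region SUVR through the inverse of the CT whole-cerebellum
equation; reference regions sit at uptake 1, so the nominal target uptake
equals the SUVR. The simulated visual read is true CL > 30 (within the
published 25–35 consensus band), with an optional label-noise rate
(default 0) standing in for human reader variability.

The "CT-like" parcellation is the generating parcellation with
boundary-local label noise: voxels within a given 6-connected depth of a
label boundary are, with a set probability, reassigned a differing
neighbour's label. The magnitude of real CT-vs-MRI parcellation
disagreement is not quantified anywhere usable, so these are free
parameters to sweep, not estimates.

What the phantom world does **not** model: anatomy, attenuation, scatter,
reconstruction artefacts, partial-volume structure beyond a stationary
Gaussian, MRI, and any systematic (non-boundary) parcellation error.
Consequently a passing test suite shows the *pipeline logic* is correct
under the stated statistical structure; it cannot certify performance on
real scans. One phantom-specific caveat: only the whole-cerebellum scale
is anchored to the generator's CL scale, so composite-reference CL values
in the phantom world sit on a shifted scale — concordance and effect-size
properties are unaffected (everything is linear), but absolute composite
CLs should not be read against the 0/100 anchors.

## Numerical and design choices

* Erosion threshold comparison `>=`; Youden tie-break toward specificity;
  ROC positivity `>=`; all pinned for bit-reproducibility.
* CL values are reported to one decimal in formatted output; full
  precision is retained in every table.
* Subjects failing any mask or grid check are excluded with a recorded
  reason and do not disturb other subjects — mirroring how failed cases
  are handled in practice.
* Problem sizes in the tests are deliberately desk-scale: cohorts of
  10–30 phantom subjects for volume-level paths, 2,000 draws for
  law-of-large-numbers checks, 200 random instances for the AUC identity,
  500–10,000 bootstrap resamples. These sizes make every property
  decisive without being wasteful.
* Recomputing the published standard-pipeline effect size (3.10) from the
  rounded published summaries gives ≈3.09; rounding of the printed means
  and SDs is sufficient to explain the last-digit wobble, which is why
  the reproduction targets are the two parcellation pipelines whose
  summaries are printed in full.

## A worked example

```{r example, eval = FALSE}
library(centiloidr)

res <- run_pipeline(list(
  n_per_group = c(YC = 8, Abeta_negative = 8, ADCI = 16),
  n_boot = 2000), seed = 7)

res$calibration$WC$fit      # CT -> FS harmonisation line
res$calibration$WC$level1   # acceptance bounds report
res$stats$effect_sizes      # ADCI-vs-YC effect sizes with bootstrap CIs
res$stats$roc$CT            # ROC with Youden-optimal cutoff
conversion_table(res$calibration)
```
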