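---
title: "Decoding regional cerebral blood flow from resting-state fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding regional cerebral blood flow from resting-state fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Regional cerebral blood flow (rCBF, mL/100g/min) is a sensitive physiological
phenotype for neuropsychiatric and metabolic illness, but the modalities that
measure it directly — arterial spin labeling (ASL), SPECT, PET — are costly,
noisy or radiation-bearing, and are absent from most large biobanks. Resting-state
fMRI (rsfMRI), by contrast, is ubiquitous, and the spectral content of the
voxel-wise BOLD signal carries information about local perfusion. `rsfCBF`
implements a voxel-wise decoder of CBF from rsfMRI spectral features with an
explicit correction for partial volume averaging (PVA), together with the
statistical machinery to validate it: regional correlation analysis, Fisher
r-to-z model comparison, Bonferroni correction, case–control Cohen's *d*
effect sizes and cross-modality effect-size agreement.

The PVA problem is central. At typical 2–3 mm acquisition resolution, a
cortical voxel mixes gray matter (GM), white matter and CSF, so the measured
CBF is depressed in proportion to the non-GM content of the voxel:

    measured(v) = occ(v) * CBF_GM(v) + (1 - occ(v)) * CBF_WM + noise,

where `occ(v)` in [0, 1] is the GM occupancy from tissue segmentation of a
T1-weighted image. Because cortical thickness — and hence occupancy — varies
regionally, and is itself reduced in illness and aging, an uncorrected decoder
confounds perfusion with anatomy. The decoder here therefore carries occupancy
as an explicit feature.

## The decoder

Per voxel, the feature vector has 57 entries:

1. **Eight band powers** of the voxel's BOLD series. The series is linearly
   detrended (which removes the mean), a one-sided periodogram is computed on
   the raw DFT grid, and ordinates are summed in eight contiguous 0.08 Hz bins
   with midpoints 0.04, 0.12, ..., 0.60 Hz. Bin membership is half-open
   (`[low, high)`), the 0 Hz ordinate is excluded. The plain periodogram
   (no Welch segmentation, no taper) is the default estimator because it is
   the simplest one consistent with a Fourier-transform power spectrum; the
   per-bin *sum* of ordinates is the default, with a per-bin mean available
   (`average = TRUE`) — the two differ only by a per-bin monotone rescaling.
2. **48 neighbour band powers**: the same 8 bands for the six face-adjacent
   neighbours, in the fixed order x−, x+, y−, y+, z−, z+. Neighbour stacking
   raises SNR because perfusion-relevant spectral structure is spatially
   smooth. At mask borders the default policy replicates the centre voxel's
   bands (avoiding a spurious power deficit); zero-fill is available.
3. **GM occupancy** (1 entry). In the uncorrected (`original`) model this
   column is kept but set to 0 for every voxel, exactly reproducing the
   uncorrected decoder as a special case of the corrected one; in
   `pva_corrected` mode it carries the occupancy value.

The regression is an epsilon-SVR with an RBF kernel (`e1071`), fit on features
and targets z-scored with training-set statistics. `C` and `gamma` are chosen
by cross-validated RMSE over a small grid (defaults `C` in {0.1, 1, 10, 100},
`gamma` centred on 1/57), with folds grouped by subject so that no subject
straddles a fold boundary, and ties broken toward the less complex model
(smaller `C`, then smaller `gamma`). The epsilon tube is fixed at 0.1 on the
standardized target scale. None of the published grids are known, so all of
these are declared configuration (`model_config()`) rather than inferred
constants.

Kernel SVR cannot be trained on every cortical voxel of every subject
(hundreds of subjects times ~2×10^5 voxels), so training pools a seeded
uniform subsample per subject (`voxels_per_subject`, default 2000). This is
the main practical deviation knob and is recorded in the model metadata.

Predictions are made voxel by voxel and averaged over an integer-labelled
bilateral atlas (34 regions in a standard Desikan–Killiany parcellation;
the phantom uses 8 bilateral parcels). Bilateral averaging is the default
output granularity because validation tables in this literature are
34-row; per-hemisphere output is available with `bilateral = FALSE`.

### Occupancy preparation

Native-resolution GM occupancy maps are smoothed with a 5 mm FWHM Gaussian
(sigma = FWHM/2.3548, converted to voxels per axis, separable convolution
with reflective boundaries) and resampled to 2 mm isotropic — block
averaging when the target spacing is an integer multiple of the input,
trilinear interpolation otherwise. Values are clipped to [0, 1] at both
ends. Constants are preserved exactly and ribbon mass is conserved to
within 1% away from grid edges.

### Statistical analyses

* **Train/test split**: a random 2/3–1/3 subject split, redrawn (up to 1000
  seeded attempts) until age (two-sample t) and sex (chi-square or Fisher)
  differ at p > 0.2 between the sides; the achieved p-values are reported.
* **Prediction accuracy**: per-region Pearson correlation across test
  subjects between predicted and measured regional CBF, p from the exact
  t-transform with n − 2 df (not the normal approximation), plus a
  whole-brain row from mask-wide means.
* **Model comparison**: Fisher r-to-z for independent samples,
  `Z = (atanh(r1) − atanh(r2)) / sqrt(1/(n1−3) + 1/(n2−3))`. The published
  comparisons are consistent with the independent-samples form even though
  both models score the same test subjects; a dependent-correlations
  variant (Steiger) is available behind `dependent = TRUE`.
* **Multiple comparisons**: Bonferroni at alpha/m with m = 34 by default
  (threshold 1.47×10⁻³).
* **Group differences**: Student's pooled-variance t and Cohen's
  `d = (mean_case − mean_control)/s_pooled`; negative d = hypoperfusion in
  cases. Welch's t and covariate residualization (age/sex) exist but are off
  by default because the reference analyses used neither.
* **Cross-modality agreement**: Pearson correlation of two cohorts'
  per-region d vectors, p from the t-transform with #regions − 2 df.

## The synthetic cohort generator

No public cohort pairs rsfMRI with CBF maps in a redistributable form, so the
package ships a generator that reproduces the statistical structure the
method assumes, making every stage testable end to end.

**Phantom.** An ellipsoidal cortical-ribbon shell in a 24×24×12 grid of 2 mm
voxels (~2300 ribbon voxels), with occupancy peaking mid-ribbon and decaying
to zero at the ribbon edges, partitioned into 8 bilateral parcels by
hemisphere and angular sector (each ≥ 10 voxels). Ribbon thickness is
modulated around the shell (±35% by default), and — as with real thin
cortex — sub-voxel ribbon thickness lowers peak occupancy. This regional
thickness variation is what gives the PVA artifact a regional structure for
the corrected model to exploit.

**Latent band powers.** Each band has a smooth log-normal spatial field
(3-voxel Gaussian smoothing, so neighbour features carry real signal) with a
1/f-like mean profile across bands. The fields form a phantom-level template;
subjects modulate it by a smooth log-scale jitter field, per-band scalar
jitter, and per-region factors described below.

**Power→CBF link.** True GM CBF is a fixed linear functional of the latent
band powers, `CBF = a0 + alpha * sum_b a_b L_b(v)`, with weights decaying
toward high frequencies and `a0`, `alpha` calibrated once per phantom so the
ribbon population has mean 60 and SD 12 mL/100g/min. The linear default keeps
recovery targets well-posed; the true in-vivo coupling direction
(power→CBF vs CBF→power) is not identifiable from validation data, and the
generator's causal direction is a modeling convenience, not a claim.

**Between-subject variability and group effects.** Regional random
intercepts (SD 6 mL/100g/min) and any case effect (`effect_map`, in Cohen's
d units times that SD) are injected *multiplicatively into the band-power
fields*, not added to CBF post hoc. This matters: it makes group differences
visible to the rsfMRI features, so the full
features→train→predict→effect-size chain can recover an injected deficit.
A subject-level occupancy exponent (log-SD 0.1) emulates anatomical
thickness variation across subjects.

**BOLD synthesis.** Per voxel, the series (default T = 240, TR = 0.8 s) is a
sum of band-limited components built from random cosine/sine amplitudes on
the DFT grid inside each bin, rescaled so each bin's one-sided periodogram
power equals the latent target exactly, plus a white broadband floor (8% of
total band power). This makes the generator exactly controllable and
oracle-friendly: the analyzer's band powers match the latent powers up to
broadband noise and detrending (median relative error ~13% at the default
settings). With TR = 0.8 s the Nyquist frequency (0.625 Hz) truncates the
top of the highest bin; the estimator flags such bins and callers opt in
with `allow_partial = TRUE`.

**Measurement.** Measured CBF follows the forward mixing model exactly, with
WM CBF 20 mL/100g/min and Gaussian noise with SD equal to 20% of the GM CBF
SD by default; at zero noise the mixing identity is exact by construction.

### What the generator does not emulate

Hemodynamic response shape, cardiac/respiratory physiological noise, scanner
drifts and motion, spatial autocorrelation of measurement noise, subcortical
structures, and any nonlinearity in the power–CBF coupling (a mild quadratic
option exists in the link only through the SVR's capacity to fit it). Tests
that pass on this generator therefore certify the pipeline's correctness and
self-consistency — recovery of known mappings, exactness of the mixing
model, directional benefit of occupancy correction — not performance on any
real scanner's data.

## Numerical choices and degenerate inputs

* Grids must match exactly across volumes (dimensions, voxel size within
  1e-4 mm, affine-derived space token); nothing resamples implicitly except
  `prepare_occupancy()`.
* Constant feature columns (e.g. the zeroed occupancy column in original
  mode) get unit scale instead of 0 in the z-scoring, so standardization
  never divides by zero.
* Zero-variance targets, empty regions, one-hemisphere regions, labels
  missing from the LUT, non-finite voxels and |r| = 1 in the z-transform are
  hard errors, not warnings.
* Determinism: one master seed fans out to named substreams (phantom
  template, demographics, per-subject simulation, voxel subsampling, CV
  folds), so stages are independently reproducible; identical inputs give
  bit-identical feature matrices.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on deliberately small instances chosen to exercise
every code path at comfortable margins: cohorts of 7–12 BOLD subjects
(500–800 training voxels per subject, single-point hyperparameter grid at
C = 10, gamma = 1/57) for the prediction-accuracy and superiority checks;
CBF-only cohorts of 400–1000 subjects for effect-size recovery and null
calibration; and the published 34-region tables for all closed-form
statistics. At these sizes the whole suite completes in minutes on one CPU.
Observed behaviour at the defaults: held-out voxel-level correlation ≈ 0.97,
mean per-region across-subject correlation ≈ 0.99 (corrected) vs ≈ 0.91
(original) with the corrected model ahead in 10 of 10 seeded replicates, and
an injected d = −0.5 deficit recovered at ≈ −0.45 with n = 200/200 — numbers
the acceptance script recomputes from scratch on every run.

## Known limitations

* The decoder is trained and validated per acquisition protocol; nothing
  here claims transfer across TRs, scanners or preprocessing pipelines.
* The uncorrected model is represented as "occupancy forced to zero" rather
  than a 56-feature model; this reproduces the reference behaviour exactly
  but means the two modes share one feature geometry.
* Subject-grouped cross-validation folds are the default; with very few
  subjects the effective fold count drops to the subject count.
* The agreement statistic treats regions as exchangeable observations; no
  spatial-autocorrelation-aware (spin-test) inference is provided, and only
  Bonferroni correction is offered, matching the reference analyses.
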