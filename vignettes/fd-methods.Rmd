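---
title: "The FD contrast: model, pipeline, and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FD contrast: model, pipeline, and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdcontrast)
```

## The signal model

Synthetic FLAIR and double inversion recovery (DIR) images can be computed
from quantitative T1/T2/proton-density maps with idealized
inversion-recovery closed forms. Under perfect 180° inversions,
instantaneous excitation and a spoiled readout,

$$S_{FLAIR} = PD \,\bigl|1 - 2e^{-TI/T_1} + e^{-TR/T_1}\bigr|\, e^{-TE_F/T_2},$$
$$S_{DIR} = PD \,\bigl|1 - 2e^{-TI_s/T_1} + 2e^{-TI_l/T_1} - e^{-TR/T_1}\bigr|\, e^{-TE_D/T_2},$$

where $TI_l$ and $TI_s$ are the first- and second-inversion-to-readout
delays of the DIR sequence. The FD contrast is the normalized difference

$$FD = \frac{S_{FLAIR} - S_{DIR}}{S_{FLAIR}}
     = 1 - \frac{A_D(T_1)}{A_F(T_1)} e^{-(TE_D - TE_F)/T_2},$$

in which the proton density cancels exactly: FD is a pure function of the
relaxation times and the sequence timings. It is high where FLAIR retains
signal but DIR suppresses it — myelin-/lipid-rich tissue with short
T1/T2 — and it decreases under demyelination-like relaxation shifts
(longer T1 and T2):

```{r physics}
fd_analytic(850, 70)    # white-matter-like tissue
fd_analytic(1300, 90)   # deep-gray-matter-like tissue
fd_analytic(950, 80)    # white matter after a demyelination-like shift
```

Default sequence timings are FLAIR TR 15,000 / TE 90 / TI 3,100 ms and DIR
TR 15,000 / TE 100 / inversion delays 3,800 and 470 ms (all configurable
through the YAML run configuration). The printed DIR inversion times of
the emulated protocol do not state their reference points; this package
interprets the longer value as first-inversion-to-readout and the shorter
as second-inversion-to-readout, the standard DIR convention, which
reproduces the intended white-matter and CSF suppression. The
$\pm e^{-TR/T_1}$ steady-state terms are negligible at TR = 15 s for brain
T1 but keep the closed forms exact. Signals are magnitudes (synthetic
images are magnitude images); a `signed` flag exposes the raw longitudinal
expression for debugging. B1/B0 inhomogeneity, slice profiles,
magnetization transfer and multi-compartment exchange are outside the
model.

## FD map derivation

`compute_fd()` derives FD voxel-wise inside a gray+white parenchyma mask
with three stabilization rules, applied in a fixed order: epsilon
exclusion (voxels whose FLAIR signal is below `epsilon_rel` — default
$10^{-6}$ — of the within-mask FLAIR maximum are removed from the mask;
these are near-zero denominators at CSF interfaces), ratio computation,
and clipping of negative FD values to zero (DIR exceeding FLAIR indicates
noise or partial-volume inversion, not tissue signal). Both counts are
recorded on the returned `fd_map`. Outside-mask voxels are `NA` in memory
and written as zeros with the mask alongside, so files remain standard
NIfTI.

`minmax_normalize()` then rescales each subject's within-mask FD values to
span exactly [0, 1], removing inter-subject intensity drift before
voxel-wise statistics; the map is rank-preserving and idempotent, and a
constant map is defined as all zeros with a degenerate flag. Group-level
ROI summaries use the *unnormalized* (clipped) maps: per-subject min–max
scaling makes every voxel's value depend on the subject's global extrema,
which would couple unaffected regions to group effects elsewhere; the
normalization exists to serve voxel-wise testing and is applied only
there. `smooth_volume()` implements separable Gaussian smoothing
(FWHM in mm, default 4) under the masked-mean convention — the masked
volume and the mask are smoothed with the same kernel and divided — so
outside-mask values never bleed in and there is no edge attenuation
inside the mask. Scaling precedes smoothing, following the pipeline's
stated order; a flag allows the reverse for sensitivity checks.

## The phantom cohort generator

No public cohort of co-registered T1/T2/PD/myelin-fraction maps exists
for this design, so the package ships a seeded generator that emulates
one: a 48³ grid at 3 mm with a CSF shell and ventricle, a deep
white-matter core carrying genu/body/splenium callosal segments, a
cortical band, and olfactory–limbic gray-matter regions (bilateral
hippocampus, insula and anterior olfactory nucleus; left amygdala,
thalamus, orbitofrontal and parahippocampal cortex), every region at
least 60 voxels so cluster-extent tests are exercised. Voxels are pure
tissue; partial-volume mixing and realistic geometry are non-goals.

Tissue means are literature-typical 3 T values — WM 850/70 ms (PD 0.70,
myelin 0.30), deep GM 1300/90 (0.85, 0.10), CSF 4300/1500 — and the
cortical band gets longer relaxation (1700/130 ms, myelin 0.08) than deep
gray matter. That last choice also serves a numerical purpose: the
per-subject min–max scaling needs stable range anchors, and the large
cortex and deep-WM compartments own the low and high FD extrema for every
subject. For the same reason those filler compartments carry reduced
between-subject variance (`filler_sd_factor`, default 0.2): in real brains
the intensity extrema come from large, stable structures, and an unstable
anchor would inject global scaling noise into every normalized map.

Subject variability is driven by a per-region *integrity latent*
$u \sim N(0, 0.12)$ that couples microstructure to relaxation the way
demyelination does: myelin scales by $(1+u)$ while T1 and T2 scale by
$(1 - 0.40u)$ and $(1 - 0.45u)$. The impaired (MCI) group additionally
receives fixed demyelination-like shifts (T1 +12%, T2 +14%, myelin −15%)
in the hippocampal, callosal (body/splenium), thalamic, amygdalar,
orbitofrontal and anterior-olfactory regions. Quantitative maps get
additive Gaussian voxel noise (3% of the tissue mean), the measured
myelin-volume-fraction (MVF) map gets noise of sd 0.02, and a small
relaxation jitter (sd 0.01) independent of myelin keeps FD from being a
deterministic function of the MVF truth.

Covariates: age is drawn from group-specific truncated normals
(HC 63.50 ± 6.55, MCI 70.35 ± 8.09 years, bounds 50–90), reproducing the
reference cohort's confounded age structure so the ANCOVA age covariate
does real work. The odor-identification score (0–20) is linear in the
subject's mean myelin fraction over the hippocampal, insular and
anterior-olfactory link regions plus Gaussian noise (sd 1.0), with slope
and intercept calibrated analytically from the noise-free group
expectations so the group means default to 16.50 and 13.94. The
between-subject and noise scales were fixed once, by design, so that the
planted effects are recoverable at the n = 16/17 scale the generator
emulates: the planted group effect is detectable by ROI ANCOVA, and the
odor–microstructure link is detectable by voxel-wise regression at
p < 0.005 with 40-voxel extent. These effect sizes are a design choice
for desk-scale power, not estimates of any real effect.

`default_cohort_config(null_effect = TRUE)` zeroes the group effects
(keeping the odor calibration) for type-I-error checks.
`default_cohort_config(mvf_independent = TRUE)` raises the MVF
measurement noise to 0.06: in that configuration the measured MVF is a
deliberately weak proxy of the latent that drives both FD and odor
identification, so the FD–odor association must survive adjustment for
voxel-wise MVF — the logic of an image-covariate (Model B style)
analysis. Under the default configuration MVF captures most of the
latent and the adjusted association is marginal by construction.

All randomness flows from one top-level seed through derived integer
sub-streams (phantom, one per subject, fold assignment), so a cohort
regenerates bit-exactly from (seed, config), and simulation functions
require an explicit seed rather than consuming hidden global RNG state.

## Statistical pipeline

*ROI analysis.* `roi_means()` averages a map over each atlas region
within the analysis mask (empty regions are flagged missing, not zero).
`ancova_group_effect()` fits `value ~ group + age` by OLS and tests the
group coefficient two-sided; p-values are reported uncorrected at the ROI
level (a Benjamini–Hochberg column is available but off by default).
`welch_t_from_summary()` and `chi2_2x2()` (Pearson, no continuity
correction) reproduce demographic-table comparisons from printed
summaries; the Welch form is the default because it reproduces the
reference table's printed p-values more closely than the pooled form,
which is also provided.

*Classification.* `crossval_classify()` mirrors the ROI-feature
classification design: features are z-scored and PCA-reduced to the
smallest component count explaining ≥85% of variance, covariates are
appended per model (1: components; 2: + age; 3: + age + odor ID), a
logistic classifier is fitted by maximum likelihood (with a tiny-ridge
IRLS fallback under separation), and performance is the pooled
cross-validated AUC — held-out scores concatenated across five stratified
folds and ranked by midrank pair counting. The scaler and PCA are fitted
inside each training fold; a whole-sample-PCA mode exists behind a flag
for fidelity experiments only, since it leaks feature structure. Folds
are stratified and deterministic given the seed. Pooled AUC concatenates
scores rather than averaging per-fold AUCs; under the null this estimator
sits slightly below 0.5 (fold-wise score offsets), which the calibration
checks account for.

*Voxel-wise analysis.* `massunivariate_regression()` fits, at every
masked voxel, `map ~ intercept + predictor + covariates` (plus that
voxel's image-covariate value when supplied) and returns t/p maps for the
predictor; rank-deficient or zero-residual voxels are flagged invalid
rather than erroring, and an image covariate that is collinear with the
base design (e.g. constant) is absorbed, reproducing the unadjusted
model. `cluster_threshold()` applies an uncorrected p threshold, a sign
restriction (positive by default, since positive clusters are the
reported direction), and a cluster-extent minimum on connected
components; connectivity defaults to 26 (the common choice in voxel-wise
packages — the emulated pipeline does not state its convention, so it is
a parameter, as is sidedness). `crossmodal_correlation()` computes
per-voxel Pearson correlations between two metrics across subjects.
No multiple-comparison correction is applied anywhere by default,
matching the uncorrected thresholds throughout (p < 0.005 with k ≥ 40
for FD–odor models, k ≥ 10 for MVF–odor, p < 0.0001 with k ≥ 100 for the
FD–MVF correspondence).

Voxel indices in cluster tables are 0-based throughout.

## Numerical choices and degenerate inputs

- FD identity: `fd_analytic()` and the `(FLAIR − DIR)/FLAIR` ratio agree
  to 1e−10 relative tolerance; the analytic form is preferred where maps
  of T1/T2 are available because it never divides by a small signal.
- `epsilon_rel` guards the ratio; exact-zero FLAIR voxels are excluded
  regardless of the relative threshold. A subject whose mask empties
  after exclusion is an error, not a silent NaN map.
- Constant FD maps normalize to zeros with a warning and a degenerate
  flag; `fwhm = 0` smoothing is the bitwise identity.
- The Gaussian kernel is truncated at 4σ and renormalized; smoothing of
  a constant field within the mask is exact to floating tolerance.
- Cluster ties (equal sizes) are ordered by peak statistic.
- Logistic separation (infinite ML coefficients) falls back to ridge
  IRLS with λ = 1e−6; held-out ranking, hence AUC, is preserved.

## What the phantom does and does not show

Passing tests on phantom cohorts demonstrate that the pipeline recovers
what was planted under its own generative assumptions: pure-tissue
regions, Gaussian noise, a linear odor–myelin link, and relaxation shifts
that move T1 and T2 together. They do not validate the biological claims
on real data — no partial-volume mixing, registration error, scanner
drift, or non-Gaussian physiological variability is simulated, and the
planted effect sizes were chosen for desk-scale power. Reported problem
sizes used throughout the validation suite: 48³ voxels at 3 mm, 16 + 17
subjects per cohort, 100 null and 50 planted-effect replicate cohorts.

## Reproducing the validation numbers

`scripts/acceptance.R --seed <s> --out <json>` regenerates everything the
package claims from scratch: demographic p-values from the printed
reference summaries, the analytic FD values and the ratio identity, null
calibration (ANCOVA false-positive rate, chance-level pooled AUC),
planted-effect recovery (ROI detection rate, classification AUC), the
FD–odor cluster geometry, and the FD–MVF correspondence map.
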