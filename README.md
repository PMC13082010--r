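# fdcontrast

Quantitative multi-parametric MRI (e.g. QALAS-style acquisitions) yields
voxel-wise T1, T2 and proton-density maps from which any
inversion-recovery contrast can be synthesized. `fdcontrast` implements
the **FD contrast** — the normalized difference of synthetic FLAIR and
double inversion recovery (DIR) images,

```
FD = (FLAIR − DIR) / FLAIR = 1 − (A_D(T1) / A_F(T1)) · exp(−(TE_D − TE_F)/T2),
```

where `A_F = |1 − 2e^(−TI/T1) + e^(−TR/T1)|` and
`A_D = |1 − 2e^(−TI_s/T1) + 2e^(−TI_l/T1) − e^(−TR/T1)|` are the
idealized recovery factors of the two sequences. Proton density cancels,
so FD is a pure function of the relaxation times: it is high in
myelin-/lipid-rich tissue whose FLAIR signal survives while DIR
suppresses it, and it drops under demyelination-like relaxation shifts.
The package is aimed at researchers studying early microstructural change
(e.g. in mild cognitive impairment and olfactory–limbic circuits) who
want a myelin-sensitive index from routinely synthesizable contrasts,
plus the statistics to evaluate it.

It provides, end to end:

- closed-form FLAIR/DIR signal models and voxel-wise contrast synthesis
  from T1/T2/PD maps (`flair_signal`, `dir_signal`, `fd_analytic`,
  `synthesize_contrast`);
- FD map derivation with masking, epsilon exclusion of near-zero FLAIR
  denominators, clipping of negative ratios, per-subject min–max
  normalization, and masked Gaussian smoothing (`compute_fd`,
  `minmax_normalize`, `smooth_volume`);
- a seeded digital phantom generator for two-group cohorts with labeled
  olfactory–limbic ROIs, demyelination-like group effects, and an
  odor-identification score linked to ROI microstructure
  (`build_label_phantom`, `simulate_cohort`);
- ROI statistics: ROI means, age-adjusted ANCOVA group comparison,
  summary-statistic Welch t and 2×2 chi-square tests, PCA reduction and
  five-fold cross-validated logistic classification with pooled AUC
  (`roi_ancova`, `crossval_classify`);
- voxel-wise regression with optional image covariate, cluster-extent
  thresholding, and cross-modal correlation maps against myelin volume
  fraction (`massunivariate_regression`, `cluster_threshold`,
  `crossmodal_correlation`);
- NIfTI/TSV/YAML I/O, a one-call pipeline (`run_pipeline`), and a thin
  CLI (`inst/cli/fdtool.R` with subcommands `simulate`, `synth`, `fd`,
  `run-all`).

## Worked example

```r
library(fdcontrast)

# analytic FD of white- vs gray-matter-like tissue at default timings
fd_analytic(850, 70)    # 0.8832752
fd_analytic(1300, 90)   # 0.6866252

# a seeded two-group phantom cohort (16 controls, 17 impaired)
cfg <- default_cohort_config()
cohort <- simulate_cohort(n_hc = 16, n_mci = 17, config = cfg, seed = 42)
cov <- cohort_covariates(cohort)

# ROI-mean FD per subject, age-adjusted group comparison
fd_tab <- cohort_roi_table(cohort, "FD")
anc <- roi_ancova(fd_tab, cov)
subset(anc, p < 0.05, select = c(roi, estimate, statistic, p))
#>                roi estimate statistic        p
#> 4          cc_body  -0.0615     -6.52 3.28e-07
#> 5      cc_splenium  -0.0605     -5.41 7.33e-06
#> 6       thalamus_l  -0.0364     -4.10 2.87e-04
#> 7    hippocampus_l  -0.0427     -5.29 1.01e-05
#> 8    hippocampus_r  -0.0377     -5.31 9.79e-06
#> 9       amygdala_l  -0.0386     -5.90 1.84e-06
#> 11 orbitofrontal_l  -0.0451     -5.80 2.48e-06
#> 12           aon_l  -0.0373     -5.71 3.14e-06
#> 13           aon_r  -0.0411     -5.22 1.24e-05

# cross-validated classification from gray-matter ROI features
cv <- crossval_classify(fd_tab, cov, model = 1, roi_set = "GM", seed = 7)
cv$auc   # 0.985
```

Negative `estimate` values are the age-adjusted impaired-minus-control
differences: FD is reduced in the regions where the phantom planted
demyelination-like shifts (hippocampus, callosal body/splenium, thalamus,
amygdala, orbitofrontal cortex, anterior olfactory nucleus), while
unaffected regions stay at chance. The pooled cross-validated AUC
summarizes how well PCA-reduced ROI features separate the groups; values
near 1 reflect the deliberately comfortable planted effect size, not a
clinical claim.

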