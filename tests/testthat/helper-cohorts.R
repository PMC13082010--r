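# Replicate-cohort summaries are expensive; compute them once per test run
# and share across test files.
.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# per-replicate summaries of null-configuration cohorts
null_replicates <- function(n_rep = 100) {
  cached(paste0("null_", n_rep), {
    cfg <- default_cohort_config(null_effect = TRUE)
    lapply(seq_len(n_rep), function(seed) {
      co <- simulate_cohort(16, 17, cfg, seed = 20000 + seed)
      cov <- cohort_covariates(co)
      tab <- cohort_roi_table(co, "FD")
      list(p = roi_ancova(tab, cov)$p,
           auc = crossval_classify(tab, cov, model = 1,
                                   seed = derive_seed(seed, 77))$auc)
    })
  })
}

# per-replicate summaries of default planted-effect cohorts
planted_replicates <- function(n_rep = 50) {
  cached(paste0("planted_", n_rep), {
    cfg <- default_cohort_config()
    lapply(seq_len(n_rep), function(seed) {
      co <- simulate_cohort(16, 17, cfg, seed = 30000 + seed)
      cov <- cohort_covariates(co)
      tab <- cohort_roi_table(co, "FD")
      anc <- roi_ancova(tab, cov)
      list(anc = anc[, c("roi", "estimate", "p")],
           auc = crossval_classify(tab, cov, model = 1,
                                   seed = derive_seed(seed, 77))$auc)
    })
  })
}

PLANTED_ROIS <- c("hippocampus_l", "hippocampus_r", "cc_body", "cc_splenium")
AFFECTED_ROIS <- c(PLANTED_ROIS, "thalamus_l", "amygdala_l",
                   "orbitofrontal_l", "aon_l", "aon_r")
UNAFFECTED_ROIS <- c("cc_genu", "insula_l", "insula_r", "parahippocampal_l",
                     "cortex", "deep_wm")
LINKED_ROIS <- c("hippocampus_l", "hippocampus_r", "insula_l", "insula_r",
                 "aon_l", "aon_r")

# smoothed, normalized FD maps plus covariates for voxel-wise tests
voxelwise_inputs <- function(seed, mvf_independent = FALSE) {
  cached(paste0("vw_", seed, "_", mvf_independent), {
    cfg <- default_cohort_config(mvf_independent = mvf_independent)
    co <- simulate_cohort(16, 17, cfg, seed = seed)
    atlas <- co$phantom
    mask <- parenchyma_mask(atlas)
    fdmaps <- lapply(co$subjects, function(s) {
      fdm <- subject_fd_map(s, atlas, cfg, normalize = TRUE)
      smooth_volume(fdm$fd, cfg$fwhm, atlas$voxel_size, fdm$mask)
    })
    mvfmaps <- lapply(co$subjects, function(s)
      smooth_volume(s$mvf_vol, cfg$fwhm, atlas$voxel_size, mask))
    list(cohort = co, atlas = atlas, mask = mask,
         cov = cohort_covariates(co), fdmaps = fdmaps, mvfmaps = mvfmaps)
  })
}

roi_voxels <- function(atlas, names) {
  ids <- atlas$label_table$label[atlas$label_table$name %in% names]
  array(atlas$labels %in% ids, dim = dim(atlas$labels))
}
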