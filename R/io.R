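#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A 3D array with attribute `voxel_size` (mm per axis).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  vol <- array(as.numeric(img), dim = dim(img))
  attr(vol, "voxel_size") <- abs(RNifti::pixdim(img))[1:3]
  vol
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' @param vol 3D array; `NA` values are written as 0 (save the mask
#'   alongside to recover definedness).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm per axis (length 3 or scalar); defaults to the
#'   array's `voxel_size` attribute, else 1 mm.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, voxel_size = NULL) {
  stopifnot(length(dim(vol)) == 3L)
  if (is.null(voxel_size)) voxel_size <- attr(vol, "voxel_size")
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  v <- vol
  v[is.na(v)] <- 0
  img <- RNifti::asNifti(array(as.numeric(v), dim = dim(vol)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read several volumes that must share one grid
#'
#' @param paths Character vector of NIfTI paths.
#' @return List of 3D arrays.
#' @export
read_volumes <- function(paths) {
  vols <- lapply(paths, read_volume)
  dims <- lapply(vols, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L)
    stop("volumes are not on a common grid", call. = FALSE)
  vols
}

config_to_plain <- function(config) {
  strip <- function(x) {
    if (inherits(x, c("ir_params", "dir_params"))) return(unclass(x))
    if (is.list(x)) return(lapply(x, strip))
    # yaml drops names of atomic vectors; keep them as maps
    if (is.numeric(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  strip(unclass(config))
}

#' Write a run configuration to YAML
#'
#' @param config A `cohort_config` (or plain list).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  plain <- config_to_plain(config)
  if (!is.null(plain$group_effects))
    plain$group_effects <- as.list(as.data.frame(plain$group_effects))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to [default_cohort_config()] values; sequence
#' parameter blocks are validated and restored to their typed records.
#'
#' @param path YAML path.
#' @return A `cohort_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_cohort_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$flair <- do.call(ir_params, as.list(raw$flair %||% unclass(default_cohort_config()$flair)))
  cfg$dir <- do.call(dir_params, as.list(raw$dir %||% unclass(default_cohort_config()$dir)))
  if (!is.null(raw$group_effects))
    cfg$group_effects <- as.data.frame(raw$group_effects,
                                       stringsAsFactors = FALSE)
  if (!is.null(raw$class_params))
    cfg$class_params <- lapply(raw$class_params, function(x) unlist(x))
  if (!is.null(raw$age)) {
    cfg$age <- raw$age
    cfg$age$hc <- unlist(raw$age$hc); cfg$age$mci <- unlist(raw$age$mci)
    cfg$age$bounds <- unlist(raw$age$bounds)
  }
  class(cfg) <- "cohort_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference cohort demographic summaries
#'
#' Printed group summary statistics (mean, sd, n per group for age,
#' education and odor identification; male/female counts) of the HC/MCI
#' reference cohort whose characteristics parameterize the phantom
#' defaults. These summaries are the inputs for
#' [welch_t_from_summary()] and [chi2_2x2()] demographic comparisons.
#'
#' @return Nested list with elements `demographics` and `gender`.
#' @export
reference_demographics <- function() {
  yaml::read_yaml(system.file("extdata", "reference_cohort.yaml",
                              package = "fdcontrast", mustWork = TRUE))
}

#' Run the full phantom pipeline
#'
#' End-to-end orchestration on one synthetic cohort: simulate, synthesize
#' FLAIR/DIR contrasts, derive FD maps, extract ROI tables, run the
#' age-adjusted ANCOVA and the cross-validated classification, run the
#' voxel-wise odor-identification regressions (with and without the MVF
#' image covariate) and the cross-modal FD-MVF correlation, and write all
#' artifacts plus a manifest (seeds, thresholds, file hashes) to
#' `out_dir`.
#'
#' @param config A `cohort_config`.
#' @param out_dir Output directory.
#' @param seed Top-level integer seed.
#' @param n_hc,n_mci Group sizes.
#' @param p_thresh,k_min Voxel-wise threshold and cluster extent for the
#'   FD-odor maps (defaults 0.005 and 40).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_cohort_config(), out_dir, seed,
                         n_hc = 16, n_mci = 17, p_thresh = 0.005, k_min = 40) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))

  if (n_hc + n_mci == 0) {
    manifest <- list(seed = seed, n_subjects = 0,
                     note = "empty cohort; nothing to analyze")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  if (n_hc < 2 || n_mci < 2)
    stop("need at least 2 subjects per group for the analysis stages",
         call. = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("simulate",
                  simulate_cohort(n_hc, n_mci, config, seed = seed))
  stage("write-cohort", write_cohort(cohort, file.path(out_dir, "cohort")))
  cov <- cohort_covariates(cohort)
  atlas <- cohort$phantom
  mask <- parenchyma_mask(atlas)

  fd_tab <- stage("roi-table", cohort_roi_table(cohort, "FD"))
  mvf_tab <- stage("roi-table", cohort_roi_table(cohort, "MVF"))
  anc_fd <- stage("ancova", roi_ancova(fd_tab, cov))
  anc_mvf <- stage("ancova", roi_ancova(mvf_tab, cov))
  utils::write.table(anc_fd, file.path(out_dir, "ancova_fd.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(anc_mvf, file.path(out_dir, "ancova_mvf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cls <- stage("classify", {
    res <- list()
    for (rs in c("all", "GM", "WM")) for (mdl in 1:3) {
      for (feat in c("FD", "MVF")) {
        tab <- if (feat == "FD") fd_tab else mvf_tab
        key <- paste(feat, rs, paste0("model", mdl), sep = "_")
        res[[key]] <- crossval_classify(tab, cov, model = mdl, roi_set = rs,
                                        seed = derive_seed(seed, 900L + mdl))$auc
      }
    }
    res
  })
  jsonlite::write_json(cls, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  vw <- stage("voxelwise", {
    fdmaps <- lapply(cohort$subjects, function(s) {
      fdm <- subject_fd_map(s, atlas, config, normalize = TRUE)
      sm <- smooth_volume(fdm$fd, config$fwhm, atlas$voxel_size, fdm$mask)
      sm
    })
    sm <- massunivariate_regression(fdmaps, predictor = cov$odor_id,
                                    covariates = cov$age, mask = mask)
    cs <- cluster_threshold(sm, p_thresh = p_thresh, k_min = k_min)
    write_volume(sm$t, file.path(out_dir, "fd_odor_t.nii.gz"),
                 atlas$voxel_size)
    write_volume(array(as.numeric(sm$valid), dim = dim(sm$valid)),
                 file.path(out_dir, "fd_odor_valid.nii.gz"), atlas$voxel_size)
    utils::write.table(cluster_table(cs, atlas),
                       file.path(out_dir, "fd_odor_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cs
  })

  cm <- stage("crossmodal", {
    fdmaps <- lapply(cohort$subjects, function(s)
      subject_fd_map(s, atlas, config, normalize = TRUE)$fd)
    mvfs <- lapply(cohort$subjects, `[[`, "mvf_vol")
    crossmodal_correlation(fdmaps, mvfs, mask)
  })
  write_volume(cm$r, file.path(out_dir, "fd_mvf_r.nii.gz"), atlas$voxel_size)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = seed, n_hc = n_hc, n_mci = n_mci,
    thresholds = list(epsilon_rel = config$epsilon_rel, fwhm = config$fwhm,
                      p_thresh = p_thresh, k_min = k_min),
    n_fd_odor_clusters = length(vw$clusters),
    hashes = as.list(tools::md5sum(files)))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
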