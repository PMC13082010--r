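#' Derive a child seed from a top-level seed
#'
#' All randomness in a cohort flows from one top-level seed through named
#' integer sub-streams (phantom = 0, subject i = i, folds, permutations),
#' keeping every derived seed a valid 32-bit integer.
#'
#' @param seed Integer top-level seed.
#' @param k Integer stream index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed %% 1000003L) * 1009 + as.double(k) * 9973 + 1) %%
               2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Fixed ROI layout (voxel offsets from the grid centre and box extents),
# designed for grids of about 48 voxels per axis at 3 mm. Offsets are in
# array index units; every box must land inside the parenchyma shell.
phantom_roi_layout <- function() {
  L <- list(
    cc_genu            = list(off = c( 8,  0,  5), dims = c(4, 4, 5), class = "WM"),
    cc_body            = list(off = c( 0,  0,  6), dims = c(8, 4, 4), class = "WM"),
    cc_splenium        = list(off = c(-8,  0,  5), dims = c(4, 4, 5), class = "WM"),
    thalamus_l         = list(off = c( 0, -5, -1), dims = c(4, 4, 4), class = "GM"),
    hippocampus_l      = list(off = c(-6, -8, -4), dims = c(5, 4, 4), class = "GM"),
    hippocampus_r      = list(off = c(-6,  8, -4), dims = c(5, 4, 4), class = "GM"),
    amygdala_l         = list(off = c( 2, -8, -5), dims = c(4, 4, 4), class = "GM"),
    parahippocampal_l  = list(off = c(-6, -8, -9), dims = c(5, 4, 3), class = "GM"),
    orbitofrontal_l    = list(off = c( 9, -5, -6), dims = c(4, 4, 4), class = "GM"),
    aon_l              = list(off = c(10, -3, -11), dims = c(5, 3, 4), class = "GM"),
    aon_r              = list(off = c(10,  3, -11), dims = c(5, 3, 4), class = "GM"),
    insula_l           = list(off = c( 2, -11, 0), dims = c(4, 4, 4), class = "GM"),
    insula_r           = list(off = c( 2,  11, 0), dims = c(4, 4, 4), class = "GM")
  )
  L
}

#' Build a labeled digital phantom
#'
#' Generates a deterministic integer-label volume emulating an ROI atlas
#' over a simplified head geometry: a CSF shell and central ventricle, a
#' deep white-matter core carrying three corpus-callosum segments
#' (genu/body/splenium), a cortical gray-matter band, and bilateral or
#' left-lateralized olfactory-limbic gray-matter blobs (hippocampus,
#' amygdala, thalamus, orbitofrontal cortex, anterior olfactory nucleus,
#' insula, parahippocampal gyrus). Voxels are pure tissue; label 0 is
#' background. The same phantom doubles as the ROI atlas for the
#' statistics modules.
#'
#' @param shape Integer length-3 grid extents; each must be >= 32 (and
#'   large enough to place every ROI, about 40 in practice).
#' @param voxel_size Numeric length-3 (or scalar) voxel edge lengths, mm.
#' @param seed Integer seed; jitters the ROI constellation by up to one
#'   voxel in-plane. The same seed and shape reproduce the phantom
#'   bit-exactly.
#' @param k_min Minimum voxels required per named region (default 60).
#' @return An object of class `label_phantom`: `labels` (3D integer
#'   array), `label_table` (data.frame: label, name, tissue_class),
#'   `voxel_size`.
#' @export
build_label_phantom <- function(shape = c(48, 48, 48), voxel_size = c(3, 3, 3),
                                seed = 1L, k_min = 60L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("shape must have 3 extents, each >= 32", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))

  centre <- (shape + 1) / 2
  rad <- 0.45 * shape
  ax <- lapply(1:3, function(k) (seq_len(shape[k]) - centre[k]) / rad[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r <- array(sqrt(r2), dim = shape)

  labels <- array(0L, dim = shape)
  labels[r <= 1] <- 3L           # cortex band placeholder
  labels[r <= 0.92] <- 4L        # deep white matter
  labels[r > 0.92 & r <= 1] <- 1L # CSF shell
  labels[r > 0.92 & r <= 1] <- 1L
  labels[r <= 0.92 & r > 0.72] <- 3L  # cortex
  labels[r <= 0.72] <- 4L             # deep WM core

  jitter <- with_seed(seed, c(sample(-1:1, 2, replace = TRUE), 0L))

  box_index <- function(off, dims) {
    ctr <- centre + off + jitter
    idx <- lapply(1:3, function(k) {
      lo <- ceiling(ctr[k] - dims[k] / 2)
      seq.int(lo, lo + dims[k] - 1L)
    })
    as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
  }

  place <- function(ijk, id, name) {
    if (any(ijk < 1L) || any(t(ijk) > shape))
      stop("phantom extents too small to place region '", name, "'",
           call. = FALSE)
    rr <- r[ijk]
    if (any(rr > 0.92))
      stop("phantom extents too small to place region '", name,
           "' inside the parenchyma", call. = FALSE)
    cur <- labels[ijk]
    if (any(cur != 3L & cur != 4L))
      stop("region '", name, "' collides with an existing region",
           call. = FALSE)
    labels[ijk] <<- id
    invisible(NULL)
  }

  # central ventricle (CSF)
  place(box_index(c(0, 0, 1), c(5, 5, 3)), 2L, "ventricle")

  layout <- phantom_roi_layout()
  tab <- data.frame(label = c(1L, 2L, 3L, 4L),
                    name = c("csf_shell", "ventricle", "cortex", "deep_wm"),
                    tissue_class = c("CSF", "CSF", "GM", "WM"),
                    stringsAsFactors = FALSE)
  next_id <- 5L
  for (nm in names(layout)) {
    place(box_index(layout[[nm]]$off, layout[[nm]]$dims), next_id, nm)
    tab <- rbind(tab, data.frame(label = next_id, name = nm,
                                 tissue_class = layout[[nm]]$class,
                                 stringsAsFactors = FALSE))
    next_id <- next_id + 1L
  }

  counts <- tabulate(labels, nbins = max(tab$label))
  small <- tab$name[counts[tab$label] < k_min]
  if (length(small))
    stop("phantom extents too small: regions below ", k_min, " voxels: ",
         paste(small, collapse = ", "), call. = FALSE)

  structure(list(labels = labels, label_table = tab,
                 voxel_size = voxel_size, shape = shape, seed = seed),
            class = "label_phantom")
}

#' Brain parenchyma mask of a phantom
#'
#' Logical mask of all GM and WM labels (the analysis mask; CSF and
#' background excluded).
#'
#' @param phantom A `label_phantom`.
#' @return Logical 3D array.
#' @export
parenchyma_mask <- function(phantom) {
  stopifnot(inherits(phantom, "label_phantom"))
  keep <- phantom$label_table$label[
    phantom$label_table$tissue_class %in% c("GM", "WM")]
  array(phantom$labels %in% keep, dim = dim(phantom$labels))
}

#' Default cohort generation configuration
#'
#' Returns the full parameter set of the synthetic two-group cohort
#' generator. Tissue means are literature-typical 3 T values; the MCI
#' group receives demyelination-like relaxation shifts (T1 +12%, T2 +14%,
#' myelin -15%) in olfactory-limbic and callosal regions; age follows the
#' reference cohort demographics (HC 63.50 +/- 6.55, MCI 70.35 +/- 8.09
#' years, truncated to 50-90); the odor-identification score is linear in
#' the subject's mean myelin fraction over hippocampal, insular and
#' anterior-olfactory-nucleus labels, with slope and intercept calibrated
#' so group means default to about 16.5 (HC) and 13.9 (MCI).
#'
#' @param null_effect If `TRUE`, zero all group effects (null cohorts for
#'   calibration checks) while keeping the odor-link calibration of the
#'   default effect configuration.
#' @param mvf_independent If `TRUE`, raise the MVF measurement noise
#'   (0.02 to 0.06) so that the measured myelin map is only a weak proxy
#'   of the microstructural latent that drives both FD and odor
#'   identification: the partially-independent-signal configuration used
#'   to exercise image-covariate-adjusted (Model B style) inference.
#' @return A named list (class `cohort_config`).
#' @export
default_cohort_config <- function(null_effect = FALSE,
                                  mvf_independent = FALSE) {
  affected <- c("hippocampus_l", "hippocampus_r", "cc_body", "cc_splenium",
                "thalamus_l", "amygdala_l", "orbitofrontal_l",
                "aon_l", "aon_r")
  eff <- data.frame(name = affected, dt1 = 0.12, dt2 = 0.14, dmyelin = -0.15,
                    stringsAsFactors = FALSE)
  cfg <- list(
    shape = c(48L, 48L, 48L),
    voxel_size = c(3, 3, 3),
    class_params = list(
      WM  = c(t1 = 850,  t2 = 70,   pd = 0.70, myelin = 0.30),
      GM  = c(t1 = 1300, t2 = 90,   pd = 0.85, myelin = 0.10),
      CSF = c(t1 = 4300, t2 = 1500, pd = 1.00, myelin = 0.00)),
    # the superficial cortical band gets longer relaxation times than deep
    # gray matter, anchoring the low end of the FD range in a large stable
    # compartment (its FD sits well below every ROI under study)
    cortex_params = c(t1 = 1700, t2 = 130, pd = 0.85, myelin = 0.08),
    group_effects = eff,
    sd_integrity = 0.12,   # between-subject sd of the per-ROI integrity latent
    filler_sd_factor = 0.2, # integrity-sd multiplier for the large filler
                            # compartments (cortex band, deep WM, CSF), so
                            # per-subject intensity anchors stay stable
    couple_t1 = 0.40,      # relative T1 change per unit integrity latent
    couple_t2 = 0.45,      # relative T2 change per unit integrity latent
    sd_relax_indep = 0.01, # relaxation jitter independent of myelin
    noise_pct = 0.03,      # voxel noise sd on T1/T2/PD maps, x tissue mean
    mvf_noise_sd = 0.02,   # voxel noise sd on the MVF map
    age = list(hc = c(mean = 63.50, sd = 6.55),
               mci = c(mean = 70.35, sd = 8.09),
               bounds = c(50, 90)),
    odor = list(target_hc = 16.50, target_mci = 13.94, sd = 1.0,
                link_rois = c("hippocampus_l", "hippocampus_r",
                              "insula_l", "insula_r", "aon_l", "aon_r")),
    flair = ir_params(),
    dir = dir_params(),
    epsilon_rel = 1e-6,
    fwhm = 4)
  if (mvf_independent) cfg$mvf_noise_sd <- 0.06
  if (null_effect) {
    cfg$odor$calibrate_effects <- eff   # keep the default odor calibration
    cfg$group_effects$dt1 <- 0
    cfg$group_effects$dt2 <- 0
    cfg$group_effects$dmyelin <- 0
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Per-region tissue parameters for a phantom under a configuration
#'
#' Expands class-level tissue means to a per-label table, attaches the MCI
#' group effects, and calibrates the odor-identification link
#' (`odor_a`, `odor_b`) from the noise-free group expectations of mean
#' myelin over the link regions.
#'
#' @param phantom A `label_phantom`.
#' @param config A `cohort_config`.
#' @return An object of class `tissue_params` bundling the per-label
#'   table, generation noise parameters and covariate distributions.
#' @export
tissue_params <- function(phantom, config = default_cohort_config()) {
  stopifnot(inherits(phantom, "label_phantom"))
  tab <- phantom$label_table
  cp <- config$class_params
  par <- do.call(rbind, lapply(tab$tissue_class, function(cl) cp[[cl]]))
  tab <- cbind(tab, as.data.frame(par))
  if (!is.null(config$cortex_params) && "cortex" %in% tab$name) {
    i <- match("cortex", tab$name)
    tab[i, c("t1", "t2", "pd", "myelin")] <- as.list(config$cortex_params)
  }
  filler <- tab$name %in% c("csf_shell", "ventricle", "cortex", "deep_wm")
  tab$u_scale <- ifelse(filler, config$filler_sd_factor %||% 1, 1)
  tab$dt1 <- 0; tab$dt2 <- 0; tab$dmyelin <- 0
  ge <- config$group_effects
  m <- match(ge$name, tab$name)
  if (anyNA(m)) stop("group_effects reference unknown regions", call. = FALSE)
  tab$dt1[m] <- ge$dt1; tab$dt2[m] <- ge$dt2; tab$dmyelin[m] <- ge$dmyelin
  # valid-range check after effects
  if (any(tab$t1 * (1 + tab$dt1) <= 0) || any(tab$t2 * (1 + tab$dt2) <= 0) ||
      any(tab$myelin * (1 + tab$dmyelin) < 0) ||
      any(tab$myelin * (1 + tab$dmyelin) > 1))
    stop("group effects push tissue parameters out of range", call. = FALSE)

  counts <- tabulate(phantom$labels, nbins = max(tab$label))[tab$label]
  link <- tab$name %in% config$odor$link_rois
  if (!any(link)) stop("no odor link regions present in phantom", call. = FALSE)
  w <- counts[link] / sum(counts[link])
  # expectations use the calibration effect set (by default the generating
  # effects; null configs keep the default-effect calibration)
  cal <- config$odor$calibrate_effects
  dmy <- tab$dmyelin
  if (!is.null(cal)) {
    dmy <- rep(0, nrow(tab))
    mm <- match(cal$name, tab$name)
    dmy[mm] <- cal$dmyelin
  }
  e_hc <- sum(w * tab$myelin[link])
  e_mci <- sum(w * tab$myelin[link] * (1 + dmy[link]))
  if (abs(e_hc - e_mci) < 1e-12) {
    odor_b <- 0
    odor_a <- config$odor$target_hc
  } else {
    odor_b <- (config$odor$target_hc - config$odor$target_mci) / (e_hc - e_mci)
    odor_a <- config$odor$target_hc - odor_b * e_hc
  }
  structure(list(table = tab, counts = counts,
                 link = tab$name[link], link_weights = w,
                 odor_a = odor_a, odor_b = odor_b, odor_sd = config$odor$sd,
                 sd_integrity = config$sd_integrity,
                 couple_t1 = config$couple_t1, couple_t2 = config$couple_t2,
                 sd_relax_indep = config$sd_relax_indep,
                 noise_pct = config$noise_pct,
                 mvf_noise_sd = config$mvf_noise_sd,
                 age = config$age),
            class = "tissue_params")
}

rtruncnorm1 <- function(u, mean, sd, lo, hi) {
  p <- pnorm(lo, mean, sd) + u * (pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
  qnorm(p, mean, sd)
}

#' Simulate one phantom subject
#'
#' Draws subject-level tissue parameters (per-region integrity latent plus
#' independent relaxation jitter), applies the MCI group effects if
#' applicable, fills T1/T2/PD and ground-truth myelin-fraction volumes by
#' label with additive Gaussian voxel noise, and generates covariates: age
#' from the group's truncated normal and an odor-identification score
#' linear in the subject's mean myelin fraction over the link regions
#' (rounded and clipped to 0-20).
#'
#' The integrity latent u couples microstructure to relaxation the way
#' demyelination does: myelin scales by (1 + u) while T1 and T2 scale by
#' (1 - c1 u) and (1 - c2 u), so lower myelin comes with longer relaxation
#' times and hence lower FD.
#'
#' @param phantom A `label_phantom`.
#' @param tissue A [tissue_params()] object.
#' @param group `"HC"` or `"MCI"`.
#' @param seed Integer seed for this subject; required (no hidden global
#'   RNG state).
#' @param id Subject identifier.
#' @param maps If `FALSE`, skip volume synthesis and return covariates and
#'   the truth record only (fast path for covariate-level checks).
#' @return An object of class `fd_subject`.
#' @export
simulate_subject <- function(phantom, tissue, group = c("HC", "MCI"), seed,
                             id = "S01", maps = TRUE) {
  stopifnot(inherits(phantom, "label_phantom"), inherits(tissue, "tissue_params"))
  group <- match.arg(group)
  if (missing(seed) || is.null(seed))
    stop("simulate_subject requires an explicit seed", call. = FALSE)

  tab <- tissue$table
  n_lab <- nrow(tab)
  with_seed(seed, {
    u_age <- runif(1)
    eps_odor <- rnorm(1, 0, tissue$odor_sd)
    u <- rnorm(n_lab, 0, tissue$sd_integrity) * tab$u_scale
    j1 <- rnorm(n_lab, 0, tissue$sd_relax_indep)
    j2 <- rnorm(n_lab, 0, tissue$sd_relax_indep)
    gmul_t1 <- if (group == "MCI") 1 + tab$dt1 else rep(1, n_lab)
    gmul_t2 <- if (group == "MCI") 1 + tab$dt2 else rep(1, n_lab)
    gmul_my <- if (group == "MCI") 1 + tab$dmyelin else rep(1, n_lab)

    t1_s <- pmax(tab$t1 * gmul_t1 * (1 - tissue$couple_t1 * u + j1), 1)
    t2_s <- pmax(tab$t2 * gmul_t2 * (1 - tissue$couple_t2 * u + j2), 1)
    pd_s <- tab$pd
    my_s <- pmin(pmax(tab$myelin * gmul_my * (1 + u), 0), 1)

    ag <- if (group == "HC") tissue$age$hc else tissue$age$mci
    age <- rtruncnorm1(u_age, ag[["mean"]], ag[["sd"]],
                       tissue$age$bounds[1], tissue$age$bounds[2])

    link_idx <- match(tissue$link, tab$name)
    link_my <- sum(tissue$link_weights * my_s[link_idx])
    odor <- round(min(max(tissue$odor_a + tissue$odor_b * link_my + eps_odor,
                          0), 20))

    truth <- data.frame(label = tab$label, name = tab$name,
                        tissue_class = tab$tissue_class,
                        t1 = t1_s, t2 = t2_s, pd = pd_s, myelin = my_s,
                        u = u, stringsAsFactors = FALSE)

    qmaps <- NULL; mvf <- NULL
    if (maps) {
      lab <- phantom$labels
      lut <- function(vals, bgval) {
        full <- rep(bgval, max(tab$label) + 1L)
        full[tab$label + 1L] <- vals
        array(full[lab + 1L], dim = dim(lab))
      }
      nvox <- length(lab)
      inb <- lab > 0L
      t1v <- lut(t1_s, 1)
      t2v <- lut(t2_s, 1)
      pdv <- lut(pd_s, 0)
      sd1 <- lut(tissue$noise_pct * tab$t1, 0)
      sd2 <- lut(tissue$noise_pct * tab$t2, 0)
      sdp <- lut(tissue$noise_pct * tab$pd, 0)
      t1v <- pmax(t1v + rnorm(nvox) * sd1, 1)
      t2v <- pmax(t2v + rnorm(nvox) * sd2, 1)
      pdv <- pmin(pmax(pdv + rnorm(nvox) * sdp, 0), 1)
      pdv[!inb] <- 0
      mvf <- lut(my_s, 0)
      noise_mvf <- rnorm(nvox) * tissue$mvf_noise_sd
      mvf <- pmin(pmax(mvf + array(noise_mvf, dim = dim(lab)), 0), 1)
      mvf[!inb] <- 0
      qmaps <- quantitative_maps(array(t1v, dim = dim(lab)),
                                 array(t2v, dim = dim(lab)),
                                 array(pdv, dim = dim(lab)),
                                 voxel_size = phantom$voxel_size)
    }
    structure(list(id = id, group = group, age = age, odor_id = odor,
                   maps = qmaps, mvf_vol = mvf, truth = truth, seed = seed),
              class = "fd_subject")
  })
}

#' Simulate a two-group phantom cohort
#'
#' Generates `n_hc` healthy-control and `n_mci` impaired subjects on a
#' shared label phantom, each from an independent sub-seed derived from
#' the top-level seed. Regenerating with the same seed and configuration
#' reproduces the cohort bit-exactly.
#'
#' @param n_hc,n_mci Group sizes (defaults 16 and 17).
#' @param config A [default_cohort_config()]-style configuration.
#' @param seed Integer top-level seed (required).
#' @param maps Generate voxel volumes (`TRUE`) or covariates only.
#' @return An object of class `fd_cohort`: `phantom`, `tissue`,
#'   `subjects` (list of `fd_subject`), `config`, `seed`.
#' @export
simulate_cohort <- function(n_hc = 16, n_mci = 17,
                            config = default_cohort_config(), seed,
                            maps = TRUE) {
  if (missing(seed) || is.null(seed))
    stop("simulate_cohort requires an explicit seed", call. = FALSE)
  stopifnot(n_hc >= 0, n_mci >= 0)
  phantom <- build_label_phantom(config$shape, config$voxel_size,
                                 seed = derive_seed(seed, 0L))
  tissue <- tissue_params(phantom, config)
  n <- n_hc + n_mci
  groups <- c(rep("HC", n_hc), rep("MCI", n_mci))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- simulate_subject(
      phantom, tissue, group = groups[i], seed = derive_seed(seed, i),
      id = sprintf("S%02d", i), maps = maps)
  }
  structure(list(phantom = phantom, tissue = tissue, subjects = subjects,
                 config = config, seed = seed, n_hc = n_hc, n_mci = n_mci),
            class = "fd_cohort")
}

#' Covariate table of a cohort
#'
#' @param cohort An `fd_cohort`.
#' @return data.frame with columns id, group, age, odor_id.
#' @export
cohort_covariates <- function(cohort) {
  stopifnot(inherits(cohort, "fd_cohort"))
  if (!length(cohort$subjects))
    return(data.frame(id = character(), group = character(),
                      age = numeric(), odor_id = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    id = vapply(cohort$subjects, `[[`, character(1), "id"),
    group = vapply(cohort$subjects, `[[`, character(1), "group"),
    age = vapply(cohort$subjects, `[[`, numeric(1), "age"),
    odor_id = vapply(cohort$subjects, function(s) as.integer(s$odor_id),
                     integer(1)),
    stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' Writes per-subject NIfTI volumes (t1, t2, pd, mvf), the label-atlas
#' NIfTI and a `covariates.tsv` (id, group, age, odor_id).
#'
#' @param cohort An `fd_cohort` generated with `maps = TRUE`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(cohort$phantom$labels, file.path(dir, "atlas.nii.gz"),
               voxel_size = cohort$phantom$voxel_size)
  for (s in cohort$subjects) {
    if (is.null(s$maps)) stop("cohort was generated without maps", call. = FALSE)
    vs <- s$maps$voxel_size
    write_volume(s$maps$t1, file.path(dir, paste0(s$id, "_t1.nii.gz")), vs)
    write_volume(s$maps$t2, file.path(dir, paste0(s$id, "_t2.nii.gz")), vs)
    write_volume(s$maps$pd, file.path(dir, paste0(s$id, "_pd.nii.gz")), vs)
    write_volume(s$mvf_vol, file.path(dir, paste0(s$id, "_mvf.nii.gz")), vs)
  }
  cov <- cohort_covariates(cohort)
  cov$age <- sprintf("%.6f", cov$age)
  utils::write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' FD map of one subject
#'
#' Convenience wrapper: synthesizes FLAIR and DIR contrasts from the
#' subject's quantitative maps and derives the FD map within the phantom
#' parenchyma mask.
#'
#' @param subject An `fd_subject` with maps.
#' @param phantom The cohort's `label_phantom`.
#' @param config The cohort configuration (sequence parameters, epsilon).
#' @param normalize Apply per-subject min-max normalization.
#' @return An `fd_map`.
#' @export
subject_fd_map <- function(subject, phantom,
                           config = default_cohort_config(),
                           normalize = FALSE) {
  stopifnot(inherits(subject, "fd_subject"))
  if (is.null(subject$maps))
    stop("subject has no quantitative maps", call. = FALSE)
  fl <- synthesize_contrast(subject$maps, config$flair, "FLAIR")
  dr <- synthesize_contrast(subject$maps, config$dir, "DIR")
  fdm <- compute_fd(fl, dr, parenchyma_mask(phantom),
                    epsilon_rel = config$epsilon_rel)
  if (normalize) fdm <- minmax_normalize(fdm)
  fdm
}
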