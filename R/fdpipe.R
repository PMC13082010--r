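#' Compute an FD map from FLAIR and DIR volumes
#'
#' Derives the voxel-wise FD contrast, FD = (FLAIR - DIR) / FLAIR, within a
#' brain parenchyma mask, applying the stabilization rules of the FD
#' pipeline:
#' \itemize{
#'   \item voxels whose FLAIR signal falls below `epsilon_rel` times the
#'     within-mask FLAIR maximum are removed from the mask (near-zero
#'     denominators, typically deep CSF or brain edges) and counted in
#'     `n_excluded`;
#'   \item negative FD values (DIR > FLAIR, from noise or partial volume)
#'     are set to zero and counted in `n_clipped`.
#' }
#' Voxels outside the (possibly reduced) mask are `NA` in the output map;
#' they are undefined rather than zero.
#'
#' @param flair,dir `contrast_volume` objects or plain 3D arrays on one
#'   grid.
#' @param mask Logical 3D array (brain parenchyma, GM+WM).
#' @param epsilon_rel Positive fraction of the within-mask FLAIR maximum
#'   below which voxels are excluded. Default `1e-6` removes only
#'   essentially zero denominators.
#' @return An object of class `fd_map`: list with `fd` (3D array, `NA`
#'   outside mask), `mask`, `n_clipped`, `n_excluded`, `normalized`
#'   (`FALSE`), `voxel_size` (if known).
#' @export
compute_fd <- function(flair, dir, mask, epsilon_rel = 1e-6) {
  voxel_size <- NULL
  if (inherits(flair, "contrast_volume")) {
    voxel_size <- flair$voxel_size
    flair <- flair$signal
  }
  if (inherits(dir, "contrast_volume")) dir <- dir$signal
  if (!identical(dim(flair), dim(dir)) || !identical(dim(flair), dim(mask)))
    stop("FLAIR, DIR and mask must share one grid", call. = FALSE)
  if (!(is.numeric(epsilon_rel) && length(epsilon_rel) == 1L && epsilon_rel > 0))
    stop("epsilon_rel must be a positive scalar", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)

  thr <- epsilon_rel * max(flair[mask])
  keep <- mask & (flair >= thr) & (flair > 0)
  n_excluded <- sum(mask) - sum(keep)
  if (!any(keep))
    stop("no voxels survive the FLAIR epsilon exclusion; degenerate subject",
         call. = FALSE)

  fd <- array(NA_real_, dim = dim(flair))
  fd[keep] <- (flair[keep] - dir[keep]) / flair[keep]
  neg <- keep & !is.na(fd) & fd < 0
  n_clipped <- sum(neg)
  fd[neg] <- 0

  structure(list(fd = fd, mask = keep, n_clipped = n_clipped,
                 n_excluded = n_excluded, normalized = FALSE,
                 degenerate = FALSE, voxel_size = voxel_size),
            class = "fd_map")
}

#' Min-max normalize an FD map within its mask
#'
#' Linearly rescales the within-mask FD values to span \[0, 1\], so the
#' lowest FD in brain tissue becomes 0 and the highest becomes 1. This
#' per-subject scaling removes inter-subject intensity drift before
#' voxel-wise statistics. Rank order of voxels is preserved and the
#' operation is idempotent. A constant map (max equals min) is defined as
#' all zeros, with the `degenerate` flag set.
#'
#' @param fdmap An `fd_map` from [compute_fd()].
#' @return The normalized `fd_map` (`normalized = TRUE`).
#' @export
minmax_normalize <- function(fdmap) {
  stopifnot(inherits(fdmap, "fd_map"))
  v <- fdmap$fd[fdmap$mask]
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warning("constant FD map; normalization yields all zeros", call. = FALSE)
    fdmap$fd[fdmap$mask] <- 0
    fdmap$degenerate <- TRUE
  } else {
    fdmap$fd[fdmap$mask] <- (v - lo) / (hi - lo)
  }
  fdmap$normalized <- TRUE
  fdmap
}

gaussian_kernel_matrix <- function(n, sigma_vox) {
  # dense Toeplitz convolution matrix for one axis, kernel truncated at
  # ~4 sigma and normalized to unit sum
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- w[o + r + 1L]
  }
  K
}

apply_axis <- function(vol, K, axis) {
  d <- dim(vol)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  dp <- dim(v)
  v <- K %*% matrix(v, nrow = dp[1])
  v <- array(v, dim = dp)
  inv <- order(perm)
  aperm(v, inv)
}

#' Gaussian smoothing of a volume within a mask
#'
#' Separable 3D Gaussian convolution with kernel width given as
#' full-width-at-half-maximum in millimetres (per-axis
#' \eqn{\sigma = FWHM / (2\sqrt{2\ln 2}) / voxel\_size}). Smoothing uses
#' the masked-mean convention: the masked volume and the mask are smoothed
#' with the same kernel and their ratio is returned, so values outside the
#' mask never bleed in and a constant field stays constant up to floating
#' tolerance. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param vol 3D array.
#' @param fwhm_mm Kernel FWHM in mm (>= 0).
#' @param voxel_size Numeric length-3 (or scalar), mm per axis.
#' @param mask Optional logical 3D array; default is the whole volume.
#' @return Smoothed 3D array; `NA` outside `mask`.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size = c(1, 1, 1), mask = NULL) {
  if (!(is.numeric(fwhm_mm) && length(fwhm_mm) == 1L && fwhm_mm >= 0))
    stop("fwhm_mm must be a non-negative scalar", call. = FALSE)
  stopifnot(length(dim(vol)) == 3L)
  if (fwhm_mm == 0) return(vol)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(vol))
  if (!identical(dim(mask), dim(vol)))
    stop("mask and volume must share one grid", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(vol))

  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  num <- vol
  num[!mask] <- 0
  den <- array(as.numeric(mask), dim = dim(vol))
  for (ax in 1:3) {
    K <- gaussian_kernel_matrix(dim(vol)[ax], sigma[ax])
    num <- apply_axis(num, K, ax)
    den <- apply_axis(den, K, ax)
  }
  out <- array(NA_real_, dim = dim(vol))
  out[mask] <- num[mask] / den[mask]
  out
}
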