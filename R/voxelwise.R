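as_subject_matrix <- function(maps, mask) {
  # list of 3D arrays (or an already-formed subjects x voxels matrix
  # restricted to mask) -> subjects x masked-voxels matrix
  if (is.matrix(maps)) return(maps)
  stopifnot(is.list(maps), length(maps) >= 1)
  idx <- which(mask)
  do.call(rbind, lapply(maps, function(v) {
    if (inherits(v, "fd_map")) v <- v$fd
    if (!identical(dim(v), dim(mask)))
      stop("all volumes must share the mask grid", call. = FALSE)
    v[idx]
  }))
}

#' Mass-univariate voxel-wise regression
#'
#' At every masked voxel, fits by least squares
#' `map value ~ intercept + predictor + covariates (+ image covariate)`
#' across subjects and tests the predictor coefficient (two-sided t).
#' When `image_covariate` volumes are supplied, that voxel's
#' image-covariate value enters the design as an additional column (e.g.
#' adjusting an FD-odor regression for local myelin volume fraction).
#' Voxels with a rank-deficient design or zero residual variance are
#' flagged invalid rather than erroring.
#'
#' @param maps List of per-subject 3D volumes (or `fd_map`s), the outcome.
#' @param predictor Per-subject scalar of interest (e.g. odor ID).
#' @param covariates Optional per-subject vector/matrix/data.frame of
#'   nuisance covariates (e.g. age).
#' @param image_covariate Optional list of per-subject 3D volumes entering
#'   voxel-wise.
#' @param mask Logical 3D array; voxels invalid (`NA`) in any subject are
#'   dropped listwise.
#' @return A `stat_map`: `t`, `p` (3D arrays, `NA` outside valid voxels),
#'   `valid` (logical 3D), `df`, `model` descriptor.
#' @export
massunivariate_regression <- function(maps, predictor, covariates = NULL,
                                      image_covariate = NULL, mask) {
  n <- length(predictor)
  if (length(maps) != n)
    stop("number of maps and predictor length differ", call. = FALSE)
  if (!is.null(image_covariate) && length(image_covariate) != n)
    stop("image covariate subject count mismatch", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  Y <- as_subject_matrix(maps, mask)
  Z <- if (!is.null(image_covariate))
    as_subject_matrix(image_covariate, mask) else NULL

  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X0 <- cbind(intercept = 1, predictor = predictor, C)
  p0 <- ncol(X0) + as.integer(!is.null(Z))
  if (n < p0 + 2) stop("too few subjects for the design", call. = FALSE)

  # listwise-complete voxels only
  ok_v <- colSums(is.na(Y)) == 0
  if (!is.null(Z)) ok_v <- ok_v & colSums(is.na(Z)) == 0

  idx <- which(mask)
  tvol <- array(NA_real_, dim = dim(mask))
  pvol <- array(NA_real_, dim = dim(mask))
  valid <- array(FALSE, dim = dim(mask))
  df <- n - p0
  jp <- 2L  # predictor column

  if (is.null(Z)) {
    qrx <- qr(X0)
    if (qrx$rank < ncol(X0))
      stop("rank-deficient base design (collinear covariates)", call. = FALSE)
    XtXinv <- chol2inv(qr.R(qrx))
    B <- XtXinv %*% crossprod(X0, Y[, ok_v, drop = FALSE])
    R <- Y[, ok_v, drop = FALSE] - X0 %*% B
    rss <- colSums(R^2)
    sigma2 <- rss / df
    se <- sqrt(XtXinv[jp, jp] * sigma2)
    tt <- B[jp, ] / se
    good <- is.finite(tt) & sigma2 > 1e-24 * pmax(colMeans(Y[, ok_v, drop = FALSE]^2), 1e-300)
    vv <- idx[ok_v]
    tvol[vv[good]] <- tt[good]
    pvol[vv[good]] <- 2 * pt(-abs(tt[good]), df)
    valid[vv[good]] <- TRUE
  } else {
    if (qr(X0)$rank < ncol(X0))
      stop("rank-deficient base design (collinear covariates)", call. = FALSE)
    sel <- which(ok_v)
    for (v in sel) {
      Xv <- cbind(X0, img = Z[, v])
      qrv <- qr(Xv)
      dfv <- df
      if (qrv$rank < ncol(Xv)) {
        # image covariate collinear with the base design (e.g. constant):
        # absorbed, fit reduces to the base model
        Xv <- X0
        qrv <- qr(Xv)
        dfv <- n - ncol(X0)
      }
      f <- .lm.fit(Xv, Y[, v])
      rss <- sum(f$residuals^2)
      sigma2 <- rss / dfv
      if (!(sigma2 > 1e-24 * max(mean(Y[, v]^2), 1e-300))) next
      Rinv <- backsolve(qr.R(qrv), diag(ncol(Xv)))
      cov_jj <- sum(Rinv[jp, ]^2)
      se <- sqrt(cov_jj * sigma2)
      if (!is.finite(se) || se == 0) next
      co <- f$coefficients[jp]
      vvox <- idx[v]
      tvol[vvox] <- co / se
      pvol[vvox] <- 2 * pt(-abs(co / se), dfv)
      valid[vvox] <- TRUE
    }
  }

  structure(list(t = tvol, p = pvol, valid = valid, df = df,
                 model = list(predictor = "predictor",
                              n_covariates = if (is.null(C)) 0L else ncol(C),
                              image_covariate = !is.null(Z),
                              n = n)),
            class = "stat_map")
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6" = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

#' Cluster-extent thresholding of a statistic map
#'
#' Thresholds a voxel-wise statistic map at an uncorrected p-value,
#' restricts to the requested effect sign, partitions the suprathreshold
#' voxels into connected components, and discards components smaller than
#' the cluster-extent threshold `k_min`. Components are found on the
#' voxel adjacency graph (6-, 18- or 26-neighbour connectivity).
#'
#' @param statmap A `stat_map` from [massunivariate_regression()] (or any
#'   list with `t`, `p`, `valid` arrays).
#' @param p_thresh Uncorrected voxel-level p threshold (e.g. 0.005).
#' @param k_min Minimum cluster extent in voxels (>= 1).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param sign `"positive"`, `"negative"` or `"two-sided"` restriction on
#'   the statistic's sign.
#' @return A `cluster_set`: list of clusters (each with `voxels` — linear
#'   indices, `ijk0` — n x 3 zero-based array indices, `size`, `peak_t`,
#'   `peak_ijk0`), sorted by size descending (ties by peak statistic),
#'   plus the thresholding parameters.
#' @export
cluster_threshold <- function(statmap, p_thresh, k_min,
                              connectivity = 26,
                              sign = c("positive", "negative", "two-sided")) {
  sign <- match.arg(sign)
  stopifnot(k_min >= 1)
  off <- connectivity_offsets(connectivity)
  stat <- if (!is.null(statmap$t)) statmap$t else statmap$r
  dims <- dim(stat)
  supra <- statmap$valid & !is.na(statmap$p) & statmap$p < p_thresh
  supra[is.na(supra)] <- FALSE
  if (sign == "positive") supra <- supra & stat > 0
  if (sign == "negative") supra <- supra & stat < 0

  params <- list(p_thresh = p_thresh, k_min = k_min,
                 connectivity = connectivity, sign = sign)
  vox <- which(supra)
  if (!length(vox))
    return(structure(list(clusters = list(), params = params, dims = dims),
                     class = "cluster_set"))

  ijk <- arrayInd(vox, dims)
  id <- seq_along(vox)
  lut <- array(0L, dim = dims)
  lut[vox] <- id
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2, off[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_id <- lut[nb[ok, , drop = FALSE]]
    src <- id[ok]
    hit <- nb_id > 0L
    if (any(hit)) edges <- rbind(edges, cbind(src[hit], nb_id[hit]))
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  clusters <- lapply(seq_len(max(comp)), function(ci) {
    sel <- comp == ci
    if (sum(sel) < k_min) return(NULL)
    vv <- vox[sel]
    tt <- stat[vv]
    pk <- which.max(abs(tt))
    list(voxels = vv, ijk0 = ijk[sel, , drop = FALSE] - 1L,
         size = sum(sel), peak_t = tt[pk],
         peak_ijk0 = ijk[sel, , drop = FALSE][pk, ] - 1L)
  })
  clusters <- Filter(Negate(is.null), clusters)
  if (length(clusters)) {
    o <- order(vapply(clusters, `[[`, numeric(1), "size"),
               vapply(clusters, function(cl) abs(cl$peak_t), numeric(1)),
               decreasing = TRUE)
    clusters <- clusters[o]
  }
  structure(list(clusters = clusters, params = params, dims = dims),
            class = "cluster_set")
}

#' Cluster table
#'
#' @param cs A `cluster_set`.
#' @param atlas Optional `label_phantom`; adds the modal ROI label under
#'   each cluster.
#' @return data.frame: id, size, peak_t, peak i/j/k (zero-based), and
#'   `roi` when an atlas is given.
#' @export
cluster_table <- function(cs, atlas = NULL) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!length(cs$clusters))
    return(data.frame(id = integer(), size = integer(), peak_t = numeric(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer()))
  out <- do.call(rbind, lapply(seq_along(cs$clusters), function(i) {
    cl <- cs$clusters[[i]]
    data.frame(id = i, size = cl$size, peak_t = cl$peak_t,
               peak_i = cl$peak_ijk0[1], peak_j = cl$peak_ijk0[2],
               peak_k = cl$peak_ijk0[3])
  }))
  if (!is.null(atlas)) {
    out$roi <- vapply(cs$clusters, function(cl) {
      labs <- atlas$labels[cl$voxels]
      labs <- labs[labs > 0]
      if (!length(labs)) return(NA_character_)
      md <- as.integer(names(sort(table(labs), decreasing = TRUE))[1])
      atlas$label_table$name[match(md, atlas$label_table$label)]
    }, character(1))
  }
  out
}

#' Voxel-wise cross-modal correlation across subjects
#'
#' Pearson correlation between two co-registered metrics (e.g. FD and
#' myelin volume fraction) computed independently at every masked voxel
#' across subjects, with a two-sided p-value from the t transform.
#' Voxels where either metric is constant across subjects are invalid.
#'
#' @param fd_maps,mvf_maps Lists of per-subject 3D volumes (or `fd_map`s),
#'   same subjects, same grid.
#' @param mask Logical 3D array.
#' @return List of class `correlation_map`: `r`, `p` (3D arrays), `valid`,
#'   `n`.
#' @export
crossmodal_correlation <- function(fd_maps, mvf_maps, mask) {
  n <- length(fd_maps)
  if (length(mvf_maps) != n)
    stop("subject count mismatch between metrics", call. = FALSE)
  if (n < 3) stop("need at least 3 subjects for correlation", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  A <- as_subject_matrix(fd_maps, mask)
  B <- as_subject_matrix(mvf_maps, mask)
  ok <- colSums(is.na(A)) == 0 & colSums(is.na(B)) == 0

  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  sa <- sqrt(colSums(Ac^2))
  sb <- sqrt(colSums(Bc^2))
  r <- colSums(Ac * Bc) / (sa * sb)
  good <- ok & sa > 0 & sb > 0 & is.finite(r)
  r[!good] <- NA
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df)

  idx <- which(mask)
  rvol <- array(NA_real_, dim = dim(mask))
  pvol <- array(NA_real_, dim = dim(mask))
  valid <- array(FALSE, dim = dim(mask))
  rvol[idx[good]] <- r[good]
  pvol[idx[good]] <- p[good]
  valid[idx[good]] <- TRUE
  structure(list(r = rvol, p = pvol, valid = valid, n = n),
            class = "correlation_map")
}
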