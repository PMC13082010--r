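#' Mean map value within each atlas region
#'
#' Averages a scalar volume over the voxels of each named region of the
#' atlas, intersected with an analysis mask. Regions with no surviving
#' voxels are `NA` (flagged missing, not zero).
#'
#' @param map An `fd_map` or a plain 3D array.
#' @param atlas A `label_phantom` (doubles as ROI atlas).
#' @param mask Optional logical 3D array; defaults to the map's own mask
#'   for `fd_map` input, otherwise all voxels.
#' @param rois Optional character vector restricting/ordering the regions;
#'   default: all GM/WM regions in atlas order.
#' @return Named numeric vector of ROI means.
#' @export
roi_means <- function(map, atlas, mask = NULL, rois = NULL) {
  stopifnot(inherits(atlas, "label_phantom"))
  if (inherits(map, "fd_map")) {
    if (is.null(mask)) mask <- map$mask
    map <- map$fd
  }
  if (!identical(dim(map), dim(atlas$labels)))
    stop("map and atlas must share one grid", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(map))
  if (!identical(dim(mask), dim(map)))
    stop("mask and map must share one grid", call. = FALSE)

  tab <- atlas$label_table
  if (is.null(rois)) rois <- tab$name[tab$tissue_class %in% c("GM", "WM")]
  ids <- tab$label[match(rois, tab$name)]
  if (anyNA(ids)) stop("unknown ROI name(s)", call. = FALSE)

  lab <- atlas$labels
  keep <- mask & lab %in% ids
  sums <- rowsum(map[keep], lab[keep])
  cnts <- rowsum(rep(1, sum(keep)), lab[keep])
  out <- rep(NA_real_, length(ids))
  m <- match(ids, as.integer(rownames(sums)))
  out[!is.na(m)] <- sums[m[!is.na(m)], 1] / cnts[m[!is.na(m)], 1]
  names(out) <- rois
  out
}

#' ROI-by-subject feature table for a cohort
#'
#' Runs the FD derivation (or reads the MVF volume) for every subject and
#' extracts per-ROI means. For FD the group analysis uses the clipped,
#' unnormalized maps; per-subject min-max scaling is reserved for
#' voxel-wise statistics (see the methods vignette).
#'
#' @param cohort An `fd_cohort` generated with maps.
#' @param metric `"FD"` or `"MVF"`.
#' @param normalize For FD only: apply per-subject min-max scaling first.
#' @param rois Optional ROI subset/order (default all GM/WM regions).
#' @return A matrix (subjects x ROIs) with attributes `metric` and
#'   `roi_class` (per-column GM/WM tag).
#' @export
cohort_roi_table <- function(cohort, metric = c("FD", "MVF"),
                             normalize = FALSE, rois = NULL) {
  stopifnot(inherits(cohort, "fd_cohort"))
  metric <- match.arg(metric)
  atlas <- cohort$phantom
  tab <- atlas$label_table
  if (is.null(rois)) rois <- tab$name[tab$tissue_class %in% c("GM", "WM")]
  mask <- parenchyma_mask(atlas)
  rows <- lapply(cohort$subjects, function(s) {
    if (metric == "FD") {
      fdm <- subject_fd_map(s, atlas, cohort$config, normalize = normalize)
      roi_means(fdm, atlas, rois = rois)
    } else {
      roi_means(s$mvf_vol, atlas, mask = mask, rois = rois)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(cohort$subjects, `[[`, character(1), "id")
  attr(out, "metric") <- metric
  attr(out, "roi_class") <- tab$tissue_class[match(rois, tab$name)]
  out
}

#' Age-adjusted group effect on a per-subject scalar (ANCOVA)
#'
#' Ordinary least squares of `value ~ intercept + group + age`, testing
#' the two-sided main effect of diagnosis while controlling for age. The
#' group is coded 0 = reference (first factor level, HC by convention),
#' 1 = comparison (MCI), so the reported estimate is the age-adjusted
#' comparison-minus-reference difference.
#'
#' @param values Numeric per-subject outcome (e.g. one ROI's mean FD).
#' @param group Two-level factor or character vector.
#' @param age Numeric covariate.
#' @return A one-row data.frame: `estimate` (adjusted difference, second
#'   level minus first), `statistic` (t), `p`, `df`, `n1`, `n2`. Zero
#'   residual variance yields an infinite statistic with `p = 0` and a
#'   `degenerate` flag.
#' @export
ancova_group_effect <- function(values, group, age) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  if (any(table(group) < 2L)) stop("need >= 2 subjects per group", call. = FALSE)
  stopifnot(length(values) == length(group), length(age) == length(group))
  g <- as.numeric(group == levels(group)[2])
  X <- cbind(1, g, age)
  if (qr(X)$rank < 3L)
    stop("singular design: group and age are collinear", call. = FALSE)
  fit <- lm(values ~ g + age)
  sm <- summary(fit)$coefficients
  est <- sm["g", "Estimate"]
  se <- sm["g", "Std. Error"]
  df <- fit$df.residual
  degenerate <- FALSE
  if (!is.finite(se) || se == 0 || sum(residuals(fit)^2) < 1e-24) {
    stat <- sign(est) * Inf
    p <- 0
    degenerate <- TRUE
  } else {
    stat <- sm["g", "t value"]
    p <- sm["g", "Pr(>|t|)"]
  }
  data.frame(estimate = est, statistic = stat, p = p, df = df,
             n1 = sum(group == levels(group)[1]),
             n2 = sum(group == levels(group)[2]),
             degenerate = degenerate)
}

#' ANCOVA table over all ROIs of a feature table
#'
#' @param roi_tab Matrix from [cohort_roi_table()] (subjects x ROIs).
#' @param covariates data.frame with columns `group` and `age` aligned
#'   with the rows.
#' @param adjust Optional p-adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default none, mirroring the
#'   uncorrected ROI-level threshold.
#' @return data.frame: roi, roi_class, estimate, statistic, p, df (and
#'   `p_adj` when requested).
#' @export
roi_ancova <- function(roi_tab, covariates, adjust = NULL) {
  stopifnot(nrow(roi_tab) == nrow(covariates))
  res <- do.call(rbind, lapply(colnames(roi_tab), function(r) {
    row <- ancova_group_effect(roi_tab[, r], covariates$group, covariates$age)
    cbind(data.frame(roi = r, stringsAsFactors = FALSE), row)
  }))
  res$roi_class <- attr(roi_tab, "roi_class")
  if (!is.null(adjust)) res$p_adj <- p.adjust(res$p, method = adjust)
  res
}

#' Welch two-sample t-test from summary statistics
#'
#' Computes the Welch statistic with Satterthwaite degrees of freedom from
#' group means, standard deviations and sizes, as needed when only printed
#' summary tables are available.
#'
#' @param m1,s1,n1 Mean, sd, size of group 1.
#' @param m2,s2,n2 Mean, sd, size of group 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 > 0, s2 > 0, n1 >= 2, n2 >= 2)
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pooled two-sample t-test from summary statistics
#'
#' Equal-variance companion to [welch_t_from_summary()].
#'
#' @inheritParams welch_t_from_summary
#' @return List with `t`, `df`, `p`.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 > 0, s2 > 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (df = 1), as appropriate for comparing
#' printed group composition counts.
#'
#' @param a,b First row counts; @param c,d second row counts.
#' @return List with `statistic`, `p`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0))
  tabm <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tabm) == 0) || any(colSums(tabm) == 0))
    stop("degenerate 2x2 table: zero margin", call. = FALSE)
  ht <- suppressWarnings(chisq.test(tabm, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' PCA reduction retaining a variance fraction
#'
#' Standardizes features (z-score; constant columns dropped with a
#' warning), then retains the smallest number of principal components
#' whose cumulative explained variance reaches `var_threshold`. Returns a
#' projection rule usable on held-out samples.
#'
#' @param features Numeric matrix (samples x features).
#' @param var_threshold Cumulative explained-variance target in (0, 1\];
#'   default 0.85.
#' @param scale. Z-score features before PCA (default `TRUE`).
#' @return List: `scores` (training scores, samples x k), `k`,
#'   `explained` (per-component variance fractions), `rotation`, `center`,
#'   `scale`, `kept` (feature names used), and `project(newdata)`.
#' @export
pca_reduce <- function(features, var_threshold = 0.85, scale. = TRUE) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 2, var_threshold > 0, var_threshold <= 1)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  sds <- apply(features, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(features)[sds == 0], collapse = ", "), call. = FALSE)
    features <- features[, sds > 0, drop = FALSE]
  }
  if (!ncol(features)) stop("no non-constant features", call. = FALSE)
  pc <- prcomp(features, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) >= var_threshold - 1e-12)[1]
  ctr <- pc$center
  scl <- if (isTRUE(scale.)) pc$scale else rep(1, ncol(features))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  kept <- colnames(features)
  project <- function(newdata) {
    newdata <- as.matrix(newdata)
    if (is.null(colnames(newdata)))
      colnames(newdata) <- paste0("V", seq_len(ncol(newdata)))
    newdata <- newdata[, kept, drop = FALSE]
    scale(newdata, center = ctr, scale = scl) %*% rot
  }
  list(scores = pc$x[, seq_len(k), drop = FALSE], k = k, explained = expl,
       rotation = rot, center = ctr, scale = scl, kept = kept,
       project = project)
}

#' Deterministic stratified k-fold assignment
#'
#' @param labels Two-level class labels.
#' @param k_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per sample (each class spread across folds).
#' @export
make_folds <- function(labels, k_folds = 5, seed = 1L) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  fold
}

#' Pooled AUC by midrank pair counting
#'
#' Area under the ROC curve for scores pooled over cross-validation
#' folds: the fraction of (positive, negative) pairs whose scores are
#' correctly ordered, ties counted one half, computed via midranks.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical or 0/1 positive-class indicator.
#' @return AUC in \[0, 1\].
#' @export
pooled_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  stopifnot(n1 > 0, n0 > 0, length(scores) == length(labels))
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Logistic regression by ML, with a small-ridge IRLS fallback when
# separation prevents convergence or produces non-finite coefficients.
fit_logistic <- function(X, y, ridge = 1e-6) {
  Xd <- cbind(1, X)
  fit <- suppressWarnings(glm.fit(Xd, y, family = binomial()))
  beta <- fit$coefficients
  if (fit$converged && all(is.finite(beta))) return(beta)
  beta <- rep(0, ncol(Xd))
  for (it in 1:100) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(Xd * w, Xd) + diag(ridge, ncol(Xd))
    beta_new <- solve(A, crossprod(Xd * w, z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Cross-validated PCA + logistic classification of a cohort
#'
#' Five-fold stratified cross-validation of a logistic-regression
#' classifier on PCA-reduced ROI features. Within each training fold the
#' features are z-scored and PCA-reduced (components retaining
#' `var_threshold` of variance); held-out subjects are projected with the
#' training rule; covariates are appended per model (Model 1: components
#' only; Model 2: plus age; Model 3: plus age and odor identification);
#' held-out scores are pooled over folds into one AUC via midrank pair
#' counting.
#'
#' @param roi_tab Feature matrix (subjects x ROIs), e.g. from
#'   [cohort_roi_table()]; for combined feature sets, cbind the tables.
#' @param covariates data.frame with `group` (two levels; second level is
#'   the positive class), `age`, `odor_id`, aligned with rows.
#' @param model 1, 2 or 3.
#' @param roi_set `"all"`, `"GM"` or `"WM"` — filters columns by the
#'   table's `roi_class` attribute (ignored if absent).
#' @param k_folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param folds Optional explicit integer fold assignment (overrides
#'   `seed`/`k_folds`-based stratified assignment).
#' @param var_threshold PCA explained-variance target (default 0.85).
#' @param whole_sample_pca Fit scaler and PCA on the full sample before
#'   cross-validation instead of per training fold (fidelity experiments
#'   only; leaks feature structure across folds). Default `FALSE`.
#' @return List of class `cv_classification`: `auc`, `scores` (held-out,
#'   subject order), `fold` assignment, `n_components` per fold, `model`,
#'   `roi_set`, `feature_set`, and per-fold fitted parameters (`fits`).
#' @export
crossval_classify <- function(roi_tab, covariates, model = 1,
                              roi_set = c("all", "GM", "WM"),
                              k_folds = 5, seed = 1L, var_threshold = 0.85,
                              whole_sample_pca = FALSE, folds = NULL) {
  roi_set <- match.arg(roi_set)
  stopifnot(model %in% 1:3, nrow(roi_tab) == nrow(covariates))
  X <- as.matrix(roi_tab)
  cls <- attr(roi_tab, "roi_class")
  if (roi_set != "all" && !is.null(cls))
    X <- X[, cls == roi_set, drop = FALSE]
  y <- factor(covariates$group)
  stopifnot(nlevels(y) == 2L)
  ypos <- as.numeric(y == levels(y)[2])

  fold <- if (is.null(folds)) make_folds(y, k_folds = k_folds, seed = seed)
          else as.integer(folds)
  stopifnot(length(fold) == length(ypos))
  k_folds <- max(fold)
  scores <- rep(NA_real_, length(ypos))
  ncomp <- integer(k_folds)
  fits <- vector("list", k_folds)

  base_pca <- if (whole_sample_pca)
    pca_reduce(X, var_threshold = var_threshold) else NULL

  covs <- function(idx) {
    switch(model,
           NULL,
           cbind(age = covariates$age[idx]),
           cbind(age = covariates$age[idx],
                 odor_id = covariates$odor_id[idx]))
  }

  for (f in seq_len(k_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!length(te)) next
    if (length(unique(ypos[tr])) < 2L)
      stop("training fold ", f, " is missing a class; stratification failed",
           call. = FALSE)
    pca <- if (whole_sample_pca) base_pca
           else pca_reduce(X[tr, , drop = FALSE], var_threshold = var_threshold)
    Ztr <- if (whole_sample_pca) pca$project(X[tr, , drop = FALSE]) else pca$scores
    Zte <- pca$project(X[te, , drop = FALSE])
    ncomp[f] <- pca$k
    Xtr <- cbind(Ztr, covs(tr))
    Xte <- cbind(Zte, covs(te))
    beta <- fit_logistic(Xtr, ypos[tr])
    scores[te] <- drop(cbind(1, Xte) %*% beta)
    fits[[f]] <- list(rotation = pca$rotation, center = pca$center,
                      scale = pca$scale, beta = beta)
  }

  structure(list(auc = pooled_auc(scores, ypos == 1), scores = scores,
                 fold = fold, n_components = ncomp, model = model,
                 roi_set = roi_set,
                 feature_set = attr(roi_tab, "metric"),
                 positive_class = levels(y)[2], fits = fits),
            class = "cv_classification")
}
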