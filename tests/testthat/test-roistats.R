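test_that("ROI means reduce to the expected arithmetic", {
  ph <- build_label_phantom(seed = 1)
  vol <- array(0.42, dim = dim(ph$labels))
  m <- roi_means(vol, ph)
  expect_true(all(abs(m - 0.42) < 1e-12))

  # two chosen voxels of one ROI average to their midpoint
  hip <- which(ph$labels == ph$label_table$label[
    ph$label_table$name == "hippocampus_l"])
  vol2 <- array(NA_real_, dim = dim(ph$labels))
  mask <- array(FALSE, dim = dim(ph$labels))
  mask[hip[1:2]] <- TRUE
  vol2[hip[1]] <- 0.2; vol2[hip[2]] <- 0.8
  m2 <- roi_means(vol2, ph, mask = mask, rois = "hippocampus_l")
  expect_equal(unname(m2), 0.5)

  # ROI fully outside the mask is flagged missing, not zero
  m3 <- roi_means(vol, ph, mask = array(FALSE, dim = dim(ph$labels)),
                  rois = "insula_r")
  expect_true(is.na(m3))
})

test_that("ANCOVA matches the hand-solved 6-row design and the normal equations", {
  values <- c(1.0, 2.0, 3.0, 1.5, 2.5, 4.0)
  group <- rep(c("HC", "MCI"), each = 3)
  age <- rep(c(60, 65, 70), 2)
  res <- ancova_group_effect(values, group, age)
  expect_equal(res$estimate, 2 / 3, tolerance = 1e-12)
  expect_equal(res$df, 3)
  # independent normal-equations oracle for statistic and p
  X <- cbind(1, as.numeric(group == "MCI"), age)
  beta <- solve(t(X) %*% X, t(X) %*% values)
  rss <- sum((values - X %*% beta)^2)
  se <- sqrt(solve(t(X) %*% X)[2, 2] * rss / 3)
  t_or <- beta[2] / se
  expect_equal(res$statistic, t_or, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_or), 3), tolerance = 1e-10)
})

test_that("ANCOVA agrees with a direct RSS minimizer on random designs", {
  set.seed(21)
  for (rep in 1:5) {
    values <- rnorm(12)
    group <- rep(c("HC", "MCI"), each = 6)
    age <- rnorm(12, 65, 7)
    res <- ancova_group_effect(values, group, age)
    g <- as.numeric(group == "MCI")
    rssf <- function(b) sum((values - b[1] - b[2] * g - b[3] * age)^2)
    opt <- optim(c(0, 0, 0), rssf, method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 1000))
    expect_equal(res$estimate, opt$par[2], tolerance = 1e-6)
  }
})

test_that("dropping the age covariate recovers the pooled two-sample t-test", {
  set.seed(22)
  v <- rnorm(14); grp <- rep(c("A", "B"), each = 7)
  fit <- lm(v ~ as.numeric(grp == "B"))
  t_lm <- summary(fit)$coefficients[2, "t value"]
  ref <- pooled_t_from_summary(mean(v[grp == "B"]), sd(v[grp == "B"]), 7,
                               mean(v[grp == "A"]), sd(v[grp == "A"]), 7)
  expect_equal(t_lm, ref$t, tolerance = 1e-10)
})

test_that("Welch tests reproduce the reference cohort's printed p-values", {
  age <- welch_t_from_summary(63.50, 6.55, 16, 70.35, 8.09, 17)
  expect_equal(age$p, 0.0118, tolerance = 0.01)
  odor <- welch_t_from_summary(16.50, 2.16, 16, 13.94, 4.49, 17)
  expect_equal(odor$p, 0.0465, tolerance = 0.01)
  edu <- welch_t_from_summary(17.38, 2.12, 16, 16.62, 3.26, 17)
  expect_equal(edu$p, 0.4325, tolerance = 0.01)
  same <- welch_t_from_summary(5, 1, 10, 5, 2, 12)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("the 2x2 chi-square matches the direct formula and the printed value", {
  g <- chi2_2x2(3, 13, 10, 7)
  expect_equal(g$p, 0.0185, tolerance = 0.01)
  expect_equal(chi2_2x2(4, 6, 4, 6)$statistic, 0)
  expect_equal(chi2_2x2(4, 6, 4, 6)$p, 1)
  # four-cell hand oracle on random tables
  set.seed(23)
  for (rep in 1:10) {
    tb <- matrix(rpois(4, 8) + 1, 2)
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    stat <- sum((tb - E)^2 / E)
    got <- chi2_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(got$statistic, stat, tolerance = 1e-10)
  }
  expect_error(chi2_2x2(0, 0, 3, 4), "margin")
})

test_that("PCA reduction retains the minimal component count", {
  set.seed(24)
  one <- matrix(rnorm(20), ncol = 1)
  r1 <- pca_reduce(one)
  expect_equal(r1$k, 1)
  expect_equal(r1$explained, 1)

  # two uncorrelated features with variance ratio exactly 9:1 (unscaled):
  # first component explains 90% >= 85% -> k = 1
  x <- c(-3, -3, 3, 3); y <- c(-1, 1, 1, -1)
  r2 <- pca_reduce(cbind(x, y), scale. = FALSE)
  expect_equal(r2$explained[1], 0.9, tolerance = 1e-12)
  expect_equal(r2$k, 1)

  full <- matrix(rnorm(50), ncol = 5)
  expect_equal(pca_reduce(full, var_threshold = 1)$k, 5)

  cst <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_warning(r3 <- pca_reduce(cst), "constant")
  expect_equal(ncol(r3$rotation) <= 1, TRUE)

  # projection rule reproduces training scores
  X <- matrix(rnorm(60), ncol = 3)
  r4 <- pca_reduce(X, var_threshold = 1)
  expect_equal(unname(r4$project(X)), unname(r4$scores), tolerance = 1e-10)
})

test_that("pooled AUC equals exhaustive pair counting and is rank-invariant", {
  set.seed(25)
  for (rep in 1:10) {
    sc <- sample(round(rnorm(14), 1))  # ties likely
    lb <- rep(c(TRUE, FALSE), 7)
    pairs <- expand.grid(i = which(lb), j = which(!lb))
    oracle <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                          ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
    expect_equal(pooled_auc(sc, lb), oracle, tolerance = 1e-12)
    # strictly monotone transform leaves AUC unchanged
    expect_equal(pooled_auc(exp(2 * sc), lb), oracle, tolerance = 1e-12)
  }
})

test_that("pooled AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  sc <- rnorm(40); lb <- rep(c(0, 1), 20)
  ref <- as.numeric(suppressMessages(pROC::auc(lb, sc, direction = "<")))
  expect_equal(pooled_auc(sc, lb), ref, tolerance = 1e-12)
})

test_that("fold assignment is deterministic, stratified and exhaustive", {
  lb <- rep(c("HC", "MCI"), c(16, 17))
  f1 <- make_folds(lb, 5, seed = 4)
  f2 <- make_folds(lb, 5, seed = 4)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  # each fold holds 3-4 HC-class and 3-4 MCI-class at these sizes
  tabs <- table(f1, lb)
  expect_true(all(tabs >= 3 & tabs <= 4))
})

test_that("a perfectly separating feature yields pooled AUC 1 for any seed", {
  n <- 20
  lbl <- rep(c("HC", "MCI"), each = n / 2)
  X <- matrix(c(rnorm(n / 2, -5, 0.1), rnorm(n / 2, 5, 0.1)), ncol = 1)
  colnames(X) <- "f"
  cov <- data.frame(group = lbl, age = rnorm(n, 65, 5), odor_id = rnorm(n))
  for (seed in c(1, 9, 31)) {
    res <- crossval_classify(X, cov, model = 1, seed = seed, k_folds = 5)
    expect_equal(res$auc, 1)
  }
})

test_that("permuted labels give chance-level pooled AUC on average", {
  set.seed(27)
  n <- 24
  X <- matrix(rnorm(n * 4), ncol = 4)
  colnames(X) <- paste0("f", 1:4)
  aucs <- vapply(1:100, function(s) {
    lbl <- sample(rep(c("HC", "MCI"), each = n / 2))
    cov <- data.frame(group = lbl, age = rnorm(n, 65, 5),
                      odor_id = sample(0:20, n, TRUE))
    crossval_classify(X, cov, model = 1, seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("test-fold labels never influence the fitted training pipeline", {
  set.seed(28)
  n <- 22
  X <- matrix(rnorm(n * 5), ncol = 5)
  colnames(X) <- paste0("f", 1:5)
  lbl <- rep(c("HC", "MCI"), each = n / 2)
  cov <- data.frame(group = lbl, age = rnorm(n, 65, 5),
                    odor_id = sample(0:20, n, TRUE))
  res1 <- crossval_classify(X, cov, model = 2, seed = 3)
  # corrupt the labels of fold 1's held-out subjects only, holding the
  # fold assignment fixed
  te <- which(res1$fold == 1)
  cov2 <- cov
  cov2$group[te] <- ifelse(cov$group[te] == "HC", "MCI", "HC")
  res2 <- crossval_classify(X, cov2, model = 2, folds = res1$fold)
  expect_identical(res1$fits[[1]], res2$fits[[1]])
  expect_equal(res1$scores[te], res2$scores[te], tolerance = 1e-12)
})

test_that("classification respects ROI-set filtering and feature tags", {
  ph <- build_label_phantom(seed = 1)
  cfg <- default_cohort_config()
  co <- simulate_cohort(8, 8, cfg, seed = 11)
  tab <- cohort_roi_table(co, "FD")
  cov <- cohort_covariates(co)
  expect_equal(attr(tab, "metric"), "FD")
  res_gm <- crossval_classify(tab, cov, model = 1, roi_set = "GM", seed = 2)
  expect_equal(res_gm$roi_set, "GM")
  expect_true(res_gm$auc >= 0 && res_gm$auc <= 1)
  res3 <- crossval_classify(tab, cov, model = 3, seed = 2)
  expect_true(all(res3$n_components >= 1))
})
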