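sim_vw_data <- function(n = 12, dims = c(5, 5, 5), img_cov = FALSE) {
  mask <- array(TRUE, dims)
  maps <- lapply(1:n, function(i) array(rnorm(prod(dims)), dims))
  pred <- rnorm(n, 10, 4)
  age <- rnorm(n, 65, 7)
  img <- if (img_cov) lapply(1:n, function(i) array(rnorm(prod(dims)), dims))
  list(maps = maps, pred = pred, age = age, img = img, mask = mask)
}

lm_oracle <- function(d, v_idx, with_img = FALSE) {
  y <- vapply(d$maps, function(m) m[v_idx], numeric(1))
  if (with_img) {
    z <- vapply(d$img, function(m) m[v_idx], numeric(1))
    fit <- lm(y ~ d$pred + d$age + z)
  } else fit <- lm(y ~ d$pred + d$age)
  summary(fit)$coefficients["d$pred", c("t value", "Pr(>|t|)")]
}

test_that("voxel-wise regression matches a per-voxel least-squares oracle", {
  set.seed(41)
  d <- sim_vw_data()
  sm <- massunivariate_regression(d$maps, d$pred, d$age, mask = d$mask)
  expect_equal(sm$df, 12 - 3)
  for (v in c(1, 37, 63, 101, 125)) {
    orc <- lm_oracle(d, v)
    expect_equal(sm$t[v], unname(orc[1]), tolerance = 1e-8)
    expect_equal(sm$p[v], unname(orc[2]), tolerance = 1e-8)
  }
})

test_that("the image-covariate path matches the oracle too", {
  set.seed(42)
  d <- sim_vw_data(img_cov = TRUE)
  sm <- massunivariate_regression(d$maps, d$pred, d$age,
                                  image_covariate = d$img, mask = d$mask)
  expect_equal(sm$df, 12 - 4)
  for (v in c(2, 50, 88, 125)) {
    orc <- lm_oracle(d, v, with_img = TRUE)
    expect_equal(sm$t[v], unname(orc[1]), tolerance = 1e-8)
    expect_equal(sm$p[v], unname(orc[2]), tolerance = 1e-8)
  }
})

test_that("degenerate voxels are flagged invalid, not crashed on", {
  set.seed(43)
  d <- sim_vw_data()
  # voxel 1: exact copy of the predictor (zero residuals); voxel 2: constant
  for (i in seq_along(d$maps)) {
    d$maps[[i]][1] <- d$pred[i]
    d$maps[[i]][2] <- 3.14
  }
  sm <- massunivariate_regression(d$maps, d$pred, covariates = NULL,
                                  mask = d$mask)
  expect_false(sm$valid[1])
  expect_false(sm$valid[2])
  expect_true(is.na(sm$t[1]) && is.na(sm$t[2]))
  expect_true(sm$valid[10])
})

test_that("predictor t-map is invariant to affine covariate rescaling and to
           a constant image covariate", {
  set.seed(44)
  d <- sim_vw_data()
  sm1 <- massunivariate_regression(d$maps, d$pred, d$age, mask = d$mask)
  sm2 <- massunivariate_regression(d$maps, d$pred, 100 + 2.5 * d$age,
                                   mask = d$mask)
  expect_equal(sm1$t, sm2$t, tolerance = 1e-9)

  # a constant image covariate is absorbed by the intercept: predictor
  # t-values identical to omitting it
  cimg <- lapply(1:12, function(i) array(7, c(5, 5, 5)))
  sm3 <- massunivariate_regression(d$maps, d$pred, d$age,
                                   image_covariate = cimg, mask = d$mask)
  expect_equal(sm3$t, sm1$t, tolerance = 1e-9)
  expect_equal(sm3$p, sm1$p, tolerance = 1e-9)
})

test_that("subject-count mismatches are structural errors", {
  d <- sim_vw_data()
  expect_error(massunivariate_regression(d$maps[-1], d$pred, d$age,
                                         mask = d$mask), "differ")
  expect_error(massunivariate_regression(d$maps, d$pred, d$age,
                                         image_covariate = d$maps[1:3],
                                         mask = d$mask), "mismatch")
})

test_that("cluster extraction keeps the 45-voxel blob and drops the 12-voxel one", {
  dims <- c(20, 20, 20)
  tvol <- array(0, dims); pvol <- array(1, dims)
  valid <- array(TRUE, dims)
  # blob A: 45 voxels (3 x 5 x 3), blob B: 12 voxels (2 x 3 x 2), disjoint
  blob_a <- expand.grid(i = 2:4, j = 2:6, k = 2:4)
  blob_b <- expand.grid(i = 12:13, j = 12:14, k = 12:13)
  for (b in list(blob_a, blob_b)) {
    idx <- as.matrix(b)
    tvol[idx] <- 5; pvol[idx] <- 1e-4
  }
  sm <- list(t = tvol, p = pvol, valid = valid)
  cs <- cluster_threshold(sm, p_thresh = 0.005, k_min = 40)
  expect_length(cs$clusters, 1)
  expect_equal(cs$clusters[[1]]$size, 45)
  # with k_min 10 both survive, ordered by size
  cs2 <- cluster_threshold(sm, p_thresh = 0.005, k_min = 10)
  expect_equal(vapply(cs2$clusters, `[[`, numeric(1), "size"), c(45, 12))
})

test_that("corner-touching voxels merge under 26- but not 6-connectivity", {
  dims <- c(6, 6, 6)
  tvol <- array(0, dims); pvol <- array(1, dims); valid <- array(TRUE, dims)
  tvol[2, 2, 2] <- 4; pvol[2, 2, 2] <- 1e-4
  tvol[3, 3, 3] <- 4; pvol[3, 3, 3] <- 1e-4
  sm <- list(t = tvol, p = pvol, valid = valid)
  expect_length(cluster_threshold(sm, 0.005, 1, connectivity = 26)$clusters, 1)
  expect_length(cluster_threshold(sm, 0.005, 1, connectivity = 6)$clusters, 2)
  expect_error(cluster_threshold(sm, 0.005, 1, connectivity = 7), "connectivity")
})

test_that("cluster partitions agree with a BFS flood-fill oracle", {
  set.seed(45)
  dims <- c(10, 10, 10)
  for (conn in c(6, 26)) {
    pvol <- array(runif(prod(dims)), dims)
    tvol <- array(abs(rnorm(prod(dims))) + 0.1, dims)
    sm <- list(t = tvol, p = pvol, valid = array(TRUE, dims))
    cs <- cluster_threshold(sm, p_thresh = 0.3, k_min = 1, connectivity = conn)
    supra <- pvol < 0.3
    oracle <- floodfill_components(supra, connectivity_offsets_for_test(conn))
    got <- lapply(cs$clusters, function(cl) sort(cl$voxels))
    want <- lapply(oracle, sort)
    # same partition regardless of ordering
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("no suprathreshold voxels yields an empty cluster set", {
  dims <- c(5, 5, 5)
  sm <- list(t = array(0.1, dims), p = array(0.9, dims),
             valid = array(TRUE, dims))
  cs <- cluster_threshold(sm, 0.005, 10)
  expect_length(cs$clusters, 0)
  expect_equal(nrow(cluster_table(cs)), 0)
})

test_that("cross-modal correlation hits the exact endpoints and the formula", {
  set.seed(46)
  dims <- c(4, 4, 4)
  mask <- array(TRUE, dims)
  a <- lapply(1:8, function(i) array(rnorm(prod(dims)), dims))
  cm1 <- crossmodal_correlation(a, a, mask)
  expect_true(all(abs(cm1$r[cm1$valid] - 1) < 1e-10))
  cm2 <- crossmodal_correlation(a, lapply(a, function(x) -x), mask)
  expect_true(all(abs(cm2$r[cm2$valid] + 1) < 1e-10))

  b <- lapply(1:8, function(i) array(rnorm(prod(dims)), dims))
  cm3 <- crossmodal_correlation(a, b, mask)
  for (v in c(1, 17, 43, 64)) {
    av <- vapply(a, function(m) m[v], numeric(1))
    bv <- vapply(b, function(m) m[v], numeric(1))
    expect_equal(cm3$r[v], cor(av, bv), tolerance = 1e-10)
    expect_equal(cm3$p[v], cor.test(av, bv)$p.value, tolerance = 1e-8)
  }
  expect_equal(cm3$n, 8)

  # constant metric across subjects -> invalid voxel
  b2 <- lapply(b, function(x) { x[1] <- 5; x })
  cm4 <- crossmodal_correlation(a, b2, mask)
  expect_false(cm4$valid[1])
  expect_error(crossmodal_correlation(a[1:2], b[1:2], mask), "3 subjects")
})
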