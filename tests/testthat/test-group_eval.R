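const_vol <- function(v, dims = c(4L, 4L, 4L)) lab_volume(array(v, dims))

full_roi <- function(vol) lab_mask(array(TRUE, dim(vol$voxels)), vol$spacing,
                                   vol$origin, vol$direction)

test_that("median_volume matches order-statistics rules and is permutation-invariant", {
  v1 <- const_vol(1); v2 <- const_vol(2); v9 <- const_vol(9)
  expect_identical(median_volume(list(v2))$voxels, v2$voxels)
  expect_equal(median_volume(list(v1, v2, v9))$voxels, const_vol(2)$voxels)
  expect_equal(median_volume(list(v1, v2, const_vol(3), const_vol(10)))$voxels,
               const_vol(2.5)$voxels)

  # random stack vs sort-based oracle, and exact permutation invariance
  stack <- lapply(1:5, function(s) rand_volume(c(5L, 5L, 5L), seed = s))
  med <- median_volume(stack)
  oracle <- apply(sapply(stack, function(v) as.numeric(v$voxels)), 1,
                  function(r) { sr <- sort(r); sr[3] })
  expect_identical(as.numeric(med$voxels), oracle)
  perm <- median_volume(stack[c(4, 1, 5, 3, 2)])
  expect_identical(perm$voxels, med$voxels)

  v_other <- rand_volume(c(5L, 5L, 5L), seed = 1, origin = c(1, 0, 0))
  expect_error(median_volume(list(stack[[1]], v_other)), "grid")
})

test_that("Costes auto-threshold agrees with the exhaustive sweep oracle", {
  roi_dims <- c(6L, 6L, 6L)
  # identical channels: thresholds descend to the minimum observed value
  set.seed(10)
  x <- array(runif(prod(roi_dims), 1, 10), roi_dims)
  chx <- lab_volume(x)
  ct <- costes_threshold(chx, chx, full_roi(chx))
  expect_equal(ct$threshold_ch1, min(x))
  expect_false(ct$no_positive_colocalization)

  # anticorrelated: flagged, thresholds at channel maxima
  chy <- lab_volume(-x + 12)
  ct2 <- costes_threshold(chx, chy, full_roi(chx))
  expect_true(ct2$no_positive_colocalization)
  expect_equal(ct2$threshold_ch1, max(x))
  expect_equal(ct2$threshold_ch2, max(-x + 12))

  # independent noise and correlated-noise instances: exact T1 agreement
  # with the brute-force candidate sweep
  for (s in 1:4) {
    set.seed(s)
    a <- round(runif(prod(roi_dims), 0, 50))
    b <- round(0.6 * a + rnorm(prod(roi_dims), 0, 12) + 20)
    cha <- lab_volume(array(a, roi_dims))
    chb <- lab_volume(array(b, roi_dims))
    got <- costes_threshold(cha, chb, full_roi(cha))
    expect_equal(got$threshold_ch1, oracle_costes_T1(a, b),
                 info = sprintf("seed %d", s))
  }
})

test_that("Manders split coefficients follow their defining sums", {
  dims <- c(4L, 4L, 4L)
  set.seed(2)
  x <- array(runif(prod(dims), 5, 10), dims)
  chx <- lab_volume(x)
  roi <- full_roi(chx)
  # complete colocalization above threshold
  ms <- manders_split(chx, chx, 1, 1, roi)
  expect_equal(ms$tM1, 1)
  expect_equal(ms$tM2, 1)

  # disjoint supports
  a <- array(0, dims); a[1:2, , ] <- 3
  b <- array(0, dims); b[3:4, , ] <- 5
  ms2 <- manders_split(lab_volume(a), lab_volume(b), 0, 0, roi)
  expect_equal(ms2$tM1, 0)
  expect_equal(ms2$tM2, 0)

  # 4-voxel worked example: brute-force sums
  dims1 <- c(4L, 1L, 1L)
  c1 <- lab_volume(array(c(10, 10, 0, 0), dims1))
  c2 <- lab_volume(array(c(10, 0, 10, 0), dims1))
  ms3 <- manders_split(c1, c2, 5, 5, full_roi(c1))
  expect_equal(ms3$tM1, 0.5)
  expect_equal(ms3$tM2, 0.5)
})

test_that("voxel correlation uses average ranks and matches a rank oracle", {
  dims <- c(4L, 1L, 1L)
  c1 <- lab_volume(array(c(1, 2, 2, 3), dims))
  c2 <- lab_volume(array(c(1, 3, 2, 4), dims))
  roi <- full_roi(c1)
  vc <- voxel_correlation(c1, c2, roi)
  oracle <- cor(rank(c(1, 2, 2, 3)), rank(c(1, 3, 2, 4)))
  expect_identical(vc$spearman_rho, oracle)

  # monotone agreement / inversion
  set.seed(3)
  x <- array(runif(64), c(4, 4, 4))
  chx <- lab_volume(x)
  expect_equal(voxel_correlation(chx, chx, full_roi(chx))$spearman_rho, 1)
  inv <- lab_volume(max(x) - x)
  expect_equal(voxel_correlation(chx, inv, full_roi(chx))$spearman_rho, -1)
  expect_error(voxel_correlation(chx, const_vol(1), full_roi(chx)),
               "constant")
})

test_that("colocalization regression is ordinary least squares", {
  set.seed(4)
  dims <- c(10L, 10L, 10L)
  x <- array(runif(prod(dims), 0, 10), dims)
  chx <- lab_volume(x)
  roi <- full_roi(chx)
  fit0 <- coloc_regression(chx, chx, roi)
  expect_equal(fit0$slope, 1, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0, tolerance = 1e-10)

  fit1 <- coloc_regression(chx, lab_volume(2 * x + 3), roi)
  expect_equal(fit1$slope, 2, tolerance = 1e-12)
  expect_equal(fit1$intercept, 3, tolerance = 1e-10)

  # noisy seeded linear data: estimate within 3 SE of the truth
  y <- 0.8 * as.numeric(x) + rnorm(prod(dims), 0, 1)
  fit2 <- coloc_regression(chx, lab_volume(array(y, dims)), roi)
  lmfit <- lm(y ~ as.numeric(x))
  se <- summary(lmfit)$coefficients[2, 2]
  expect_lt(abs(fit2$slope - 0.8), 3 * se)
  expect_equal(fit2$slope, unname(coef(lmfit)[2]), tolerance = 1e-9)
})

test_that("all colocalization metrics ignore voxels outside the ROI", {
  set.seed(5)
  dims <- c(8L, 8L, 8L)
  x <- array(round(runif(prod(dims), 0, 40)), dims)
  y <- array(round(0.7 * x + rnorm(prod(dims), 0, 6) + 10), dims)
  roi_vox <- array(FALSE, dims); roi_vox[3:6, 3:6, 3:6] <- TRUE
  roi <- lab_mask(roi_vox)
  base <- coloc_analysis(lab_volume(y), lab_volume(x), roi)
  expect_equal(base$n_voxels, sum(roi_vox))

  # corrupt everything outside the ROI
  x2 <- x; y2 <- y
  x2[!roi_vox] <- 999 * runif(sum(!roi_vox))
  y2[!roi_vox] <- -500 * runif(sum(!roi_vox))
  corrupted <- coloc_analysis(lab_volume(y2), lab_volume(x2), roi)
  for (f in c("costes_threshold_ch1", "costes_threshold_ch2", "manders_tM1",
              "manders_tM2", "pearson_r", "spearman_rho",
              "regression_slope", "regression_intercept")) {
    expect_identical(corrupted[[f]], base[[f]], info = f)
  }
})

test_that("Manders coefficients respect opposite-channel rescaling", {
  set.seed(6)
  dims <- c(6L, 6L, 6L)
  x <- array(runif(prod(dims), 0, 10), dims)
  y <- array(runif(prod(dims), 0, 10), dims)
  roi <- full_roi(lab_volume(x))
  base <- manders_split(lab_volume(x), lab_volume(y), 4, 5, roi)
  # scaling ch2 by k and its threshold by k leaves tM1 unchanged (and tM2,
  # which is a ratio of ch2 sums)
  scaled <- manders_split(lab_volume(x), lab_volume(3 * y), 4, 15, roi)
  expect_equal(scaled$tM1, base$tM1, tolerance = 1e-12)
  expect_equal(scaled$tM2, base$tM2, tolerance = 1e-12)
})
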