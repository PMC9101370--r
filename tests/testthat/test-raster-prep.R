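rgb_raster <- function(R, G, B, res = 1) {
  d <- dim(R)
  a <- array(0, c(d[1], d[2], 3))
  a[, , 1] <- R; a[, , 2] <- G; a[, , 3] <- B
  et_raster(a, res = res)
}

test_that("vegetation indices follow their ratio definitions", {
  # G = R everywhere: both indices zero
  m <- matrix(0.3, 4, 5)
  r0 <- rgb_raster(m, m, matrix(0.1, 4, 5))
  expect_true(all(compute_index(r0, "VARI")$values == 0))
  expect_true(all(compute_index(r0, "VI")$values == 0))
  # direct arithmetic spot checks
  r1 <- rgb_raster(matrix(0.2), matrix(0.4), matrix(0.1))
  expect_equal(compute_index(r1, "VARI")$values[1, 1], 0.4)
  r2 <- rgb_raster(matrix(0.1), matrix(0.3), matrix(0.0))
  expect_equal(compute_index(r2, "VI")$values[1, 1], 0.5)
  # byte imagery is normalized by 255 first; ratios are scale-invariant
  r3 <- rgb_raster(matrix(51), matrix(102), matrix(25.5))
  expect_equal(compute_index(r3, "VARI")$values[1, 1],
               compute_index(r1, "VARI")$values[1, 1], tolerance = 1e-12)
  # zero denominator becomes nodata
  r4 <- rgb_raster(matrix(0.1), matrix(-0.1), matrix(0.0))
  expect_true(is.na(compute_index(r4, "VI")$values[1, 1]))
  expect_error(compute_index(et_raster(matrix(1, 2, 2)), "VI"), "3-band")
})

test_that("LAI regression selects the better index and matches the normal equations", {
  withr::with_seed(41, vari <- runif(20, 0, 0.6))
  pts <- tibble::tibble(lai = 2 * vari + 1, vi = runif(20, 0, 0.5), vari = vari)
  m <- fit_lai_model(pts)
  expect_equal(m$kind, "VARI")
  expect_equal(m$slope, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  # equal R^2 (identical columns): VARI wins the tie
  tie <- tibble::tibble(lai = 2 * vari + 1, vi = vari, vari = vari)
  expect_equal(fit_lai_model(tie)$kind, "VARI")
  # noisy fit equals the closed-form normal-equations estimate
  withr::with_seed(42, {
    x <- runif(30); y <- 3 * x + 0.5 + rnorm(30, sd = 0.2)
  })
  mn <- fit_lai_model(tibble::tibble(lai = y, vi = NA_real_, vari = x))
  sxx <- sum((x - mean(x))^2)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(mn$slope, slope_o, tolerance = 1e-10)
  expect_equal(mn$intercept, mean(y) - slope_o * mean(x), tolerance = 1e-10)
  # scale equivariance: scaling LAI scales both coefficients, R^2 unchanged
  ms <- fit_lai_model(tibble::tibble(lai = 3.7 * y, vi = NA_real_, vari = x))
  expect_equal(ms$slope, 3.7 * mn$slope, tolerance = 1e-9)
  expect_equal(ms$intercept, 3.7 * mn$intercept, tolerance = 1e-9)
  expect_equal(ms$r_squared, mn$r_squared, tolerance = 1e-12)
  # broom-style accessors
  expect_equal(glance(mn)$r.squared, mn$r_squared)
  expect_equal(nrow(tidy(mn)), 2)
  # degenerate: constant index
  expect_error(fit_lai_model(tibble::tibble(lai = 1:3, vi = 1, vari = 2)),
               "degenerate")
})

test_that("LAI maps apply the regression per pixel with a zero floor", {
  m <- structure(list(kind = "VARI", slope = 2, intercept = 1,
                      r_squared = 1, n_points = 10),
                 class = "lai_model")
  idx <- et_raster(matrix(0, 3, 3))
  expect_true(all(lai_map(m, idx)$values == 1))
  neg <- et_raster(matrix(-2, 2, 2))
  expect_true(all(lai_map(m, neg)$values == 0))
  withr::with_seed(43, v <- matrix(runif(30, -0.2, 0.6), 5, 6))
  got <- lai_map(m, et_raster(v))
  expect_equal(got$values, pmax(2 * v + 1, 0))
  expect_error(lai_map(m, idx, kind = "VI"), "does not match")
})

test_that("green classification separates vegetation from gray surfaces", {
  d <- c(6, 6)
  green <- rgb_raster(matrix(0.2, d[1], d[2]), matrix(0.6, d[1], d[2]),
                      matrix(0.2, d[1], d[2]))
  expect_true(all(green_mask(green)$values == 1))
  gray <- rgb_raster(matrix(0.4, d[1], d[2]), matrix(0.4, d[1], d[2]),
                     matrix(0.4, d[1], d[2]))
  expect_true(all(green_mask(gray)$values == 0))
  # half/half composite: mask fraction exactly one half
  R <- matrix(0.4, d[1], d[2]); G <- matrix(0.4, d[1], d[2]); B <- G
  G[, 1:3] <- 0.6; R[, 1:3] <- 0.2; B[, 1:3] <- 0.2
  half <- green_mask(rgb_raster(R, G, B))
  expect_equal(mean(half$values), 0.5)
})

test_that("cover fractions aggregate sub-pixel masks and respect site modes", {
  # checkerboard at 2x the target resolution: every cell half covered
  chk <- matrix(rep(c(1, 0), 8), 4, 4)
  mask <- et_raster(chk, res = 0.5)
  target <- et_raster(matrix(0, 2, 2), res = 1)
  fr <- fraction_raster(mask, target)
  expect_true(all(fr$values == 0.5))
  ones <- et_raster(matrix(1, 4, 4), res = 0.5)
  expect_true(all(fraction_raster(ones, target)$values == 1))
  # random mask: per-cell counting oracle and global conservation
  withr::with_seed(44, rm_ <- matrix(runif(64) < 0.4, 8, 8) + 0)
  mr <- et_raster(rm_, res = 0.5)
  t2 <- et_raster(matrix(0, 4, 4), res = 1)
  fr2 <- fraction_raster(mr, t2)
  oracle <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4)
    oracle[i, j] <- mean(rm_[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(fr2$values, oracle, tolerance = 1e-12)
  expect_true(all(fr2$values >= 0 & fr2$values <= 1))
  expect_equal(mean(fr2$values), mean(rm_), tolerance = 1e-9)
  # site modes pin the complementary fraction to one
  gl <- fraction_raster(mr, t2, site = "grassland")
  expect_true(all(gl$f_c$values == 1))
  expect_equal(gl$f_g$values, oracle, tolerance = 1e-12)
  cl <- fraction_raster(mr, t2, site = "cropland")
  expect_true(all(cl$f_g$values == 1))
  expect_equal(cl$f_c$values, oracle, tolerance = 1e-12)
  # CRS mismatch refused
  bad <- et_raster(rm_, res = 0.5, crs = "other")
  expect_error(fraction_raster(bad, t2), "CRS mismatch")
})

test_that("green-mask fraction of a synthetic scene matches its construction", {
  cover <- et_raster(matrix(0.5, 10, 10), res = 1)
  sc <- synth_rgb_scene(cover, res = 0.25, seed = 6)
  fr <- fraction_raster(green_mask(sc$rgb), cover)
  expect_equal(fr$values, resample_to_grid(sc$mask, cover)$values,
               tolerance = 1e-12)
  expect_equal(mean(fr$values), 0.5, tolerance = 0.06)
})

test_that("grid resampling preserves means and categories", {
  const <- et_raster(matrix(7, 8, 8), res = 0.5)
  tgt <- et_raster(matrix(0, 4, 4), res = 1)
  expect_true(all(resample_to_grid(const, tgt, "mean")$values == 7))
  withr::with_seed(45, v <- matrix(runif(64), 8, 8))
  r <- et_raster(v, res = 0.5)
  got <- resample_to_grid(r, tgt, "mean")
  oracle <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4)
    oracle[i, j] <- mean(v[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(got$values, oracle, tolerance = 1e-9)
  # nearest keeps original categories only
  cats <- et_raster(matrix(sample(c(1, 2, 5), 64, TRUE), 8, 8), res = 0.5)
  near <- resample_to_grid(cats, tgt, "nearest")
  expect_true(all(near$values %in% c(1, 2, 5)))
  # nodata-aware mean
  v2 <- v; v2[1, 1] <- NA
  got2 <- resample_to_grid(et_raster(v2, res = 0.5), tgt, "mean")
  expect_equal(got2$values[1, 1], mean(v2[1:2, 1:2], na.rm = TRUE))
  # disjoint extents
  far <- et_raster(matrix(1, 2, 2), xmin = 100, ymax = 102, res = 1)
  expect_error(resample_to_grid(far, tgt), "disjoint")
})

test_that("surface inputs end up co-registered on the thermal grid", {
  t_rad <- et_raster(matrix(25, 6, 6), res = 1)
  lai_fine <- et_raster(matrix(1.5, 12, 12), res = 0.5)
  fc <- et_raster(matrix(0.8, 6, 6), res = 1)
  fg <- et_raster(matrix(1, 6, 6), res = 1)
  si <- surface_inputs(t_rad, lai_fine, fc, fg)
  for (nm in c("lai", "f_c", "f_g")) {
    expect_equal(dim(si[[nm]]$values), dim(t_rad$values))
    expect_equal(si[[nm]]$res, 1)
  }
  expect_true(all(si$lai$values == 1.5))
  bad <- et_raster(matrix(1.4, 6, 6), res = 1)
  expect_error(surface_inputs(t_rad, lai_fine, bad, fg), "f_c outside")
})
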