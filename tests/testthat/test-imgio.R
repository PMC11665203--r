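# Image container, TIFF round-trips, projection, equalization,
# background estimation.

test_that("intensity_image validates its contract", {
  m <- matrix(runif(16), 4)
  img <- intensity_image(m, 2000 / 512, "PAM")
  expect_s3_class(img, "intensity_image")
  expect_equal(img$pixel_pitch_um, 3.90625)
  expect_error(intensity_image(m - 1), "non-negative")
  expect_error(intensity_image(matrix(c(1, NA, 1, 1), 2)), "finite")
  expect_error(intensity_image(m, pixel_pitch_um = 0), "positive")
  expect_equal(image_area_mm2(intensity_image(
    matrix(0, 512, 512), 2000 / 512)), 4, tolerance = 1e-12)
})

test_that("16-bit TIFF round-trip is bit-exact", {
  set.seed(1)
  m <- matrix(sample(0:65535, 64 * 48, replace = TRUE), 48, 64)
  f <- withr::local_tempfile(fileext = ".tif")
  save_image(m, f)
  back <- load_image(f, 2000 / 512)
  expect_identical(back$pixels, m + 0)   # numeric but exact
  expect_equal(back$pixel_pitch_um, 2000 / 512)
})

test_that("float TIFF round-trip preserves fractional images", {
  set.seed(2)
  m <- matrix(runif(32 * 32), 32)
  f <- withr::local_tempfile(fileext = ".tif")
  save_image(m, f)
  expect_equal(load_image(f)$pixels, m, tolerance = 1e-7)
})

test_that("multi-page stacks load as volumes and RGB-style input errors", {
  set.seed(7)
  a <- array(runif(8 * 8 * 5), c(8, 8, 5))
  f <- withr::local_tempfile(fileext = ".tif")
  pamvasc:::write_tiff_stack(a, f)
  back <- load_volume(f)
  expect_equal(back, a, tolerance = 1e-7)
  expect_error(load_image(f), "multi-page")
  pamvasc:::write_tiff_gray(a[, , 1] * 100, f, bits = 32L)
  expect_error(load_volume(f), "multi-page")
  expect_error(suppressWarnings(load_image("no-such-file.tif")))
})

test_that("project_volume takes the envelope maximum along depth", {
  # constant along depth
  vol <- array(3, c(4, 5, 16))
  expect_equal(project_volume(vol)$pixels, matrix(3, 4, 5),
               tolerance = 1e-9)
  # pure sinusoid of amplitude A along depth -> envelope ~ A
  A <- 2.5
  nz <- 64
  carrier <- sin(2 * pi * 8 * seq_len(nz) / nz)
  vol <- array(rep(A * carrier, each = 6 * 6), c(6, 6, nz))
  vol <- aperm(vol, c(1, 2, 3))
  expect_equal(max(abs(project_volume(vol)$pixels - A)) / A, 0,
               tolerance = 0.02)
  # 2-D input passes through with a warning
  expect_warning(p <- project_volume(matrix(1, 3, 3)), "unchanged")
  expect_equal(p$pixels, matrix(1, 3, 3))
})

test_that("projection dominates the envelope at every depth", {
  set.seed(3)
  vol <- array(runif(8 * 8 * 32), c(8, 8, 32))
  env <- pamvasc:::envelope_volume(vol)
  proj <- project_volume(vol)$pixels
  expect_true(all(proj >= apply(env, c(1, 2), max) - 1e-9))
})

test_that("equalize maps ranks to an approximately uniform law", {
  set.seed(4)
  m <- matrix(rexp(101 * 101), 101)
  e <- equalize(m)
  expect_true(all(e >= 0 & e <= 1))
  # monotone in ranks: equal inputs -> equal outputs
  m2 <- matrix(c(1, 1, 2, 3), 2)
  e2 <- equalize(m2)
  expect_equal(e2[1, 1], e2[2, 1])
  expect_true(e2[1, 2] > e2[1, 1])
  # KS distance to uniform
  ks <- suppressWarnings(stats::ks.test(as.vector(e), "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  # fixed point: already-uniform image survives up to quantization
  u <- matrix(seq(0, 1, length.out = 64 * 64), 64)
  expect_lt(max(abs(equalize(u) - u)), 2 / 256)
  # idempotence up to quantization
  expect_lt(max(abs(equalize(e) - e)), 2 / 256)
  # constant image: warning + zeros
  expect_warning(z <- equalize(matrix(5, 4, 4)), "constant")
  expect_equal(z, matrix(0, 4, 4))
})

test_that("background estimation: roi mean, automatic fallback, covariance", {
  m <- matrix(5, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[1:3, 1:3] <- TRUE
  expect_equal(estimate_background(m, roi)$level, 5)
  expect_error(estimate_background(m, matrix(FALSE, 10, 10)), "empty roi")
  expect_error(estimate_background(m, roi[1:9, 1:9, drop = FALSE]),
               "same shape")
  # vessel-free Gaussian noise: midmean ~ mu within 3 standard errors
  set.seed(5)
  n <- 200
  g <- matrix(rnorm(n * n, 50, 5), n)
  est <- estimate_background(g)
  expect_lt(abs(est$level - 50), 3 * 5 / sqrt(n * n / 2))
  # translation covariance
  est2 <- estimate_background(g + 7)
  expect_equal(est2$level, est$level + 7, tolerance = 1e-9)
})

test_that("automatic background lands near the generator's level", {
  spec <- phantom_spec(n_trees = 4, seed = 11)
  ph <- generate_vessel_phantom(spec)
  est <- estimate_background(ph$image)
  expect_lt(abs(est$level - spec$background_level),
            0.1 * spec$background_level)
})
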