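# Hessian eigenvalues and single-scale Frangi vesselness, checked against
# brute-force oracles (helper-oracle.R).

test_that("constant images have zero Hessian and zero vesselness", {
  m <- matrix(7, 32, 32)
  eig <- hessian_eigenvalues(m, 2)
  expect_equal(max(abs(eig$l1)), 0)
  expect_equal(max(abs(eig$l2)), 0)
  v <- frangi(m, vesselness_params(kernel_px = 3))
  expect_equal(max(v$values), 0)
})

test_that("separable quadratic gives eigenvalues ~ {2a, 2b} off-boundary", {
  n <- 64
  a <- 0.003; b <- -0.001
  x <- matrix(rep(seq_len(n) - n / 2, each = n), n)
  y <- t(x)
  sigma <- 2
  img <- a * x^2 + b * y^2 + 10
  img <- img - min(img)
  eig <- hessian_eigenvalues(img, sigma)
  core <- 20:44
  # gamma-normalization multiplies by sigma^2; smoothing leaves a
  # quadratic's second derivatives unchanged
  got <- sort(c(mean(eig$l1[core, core]), mean(eig$l2[core, core])))
  want <- sort(sigma^2 * c(2 * a, 2 * b))
  expect_equal(got, want, tolerance = 0.01)
})

test_that("eigenvalue fields match the brute-force oracle to 1e-6", {
  set.seed(10)
  for (rep in 1:2) {
    m <- gaussian_smooth(matrix(runif(48 * 48), 48), 1)
    eig <- hessian_eigenvalues(m, 1.5)
    orc <- oracle_hessian_eig(m, 1.5)
    scale <- max(abs(orc$l2))
    expect_lt(max(abs(eig$l1 - orc$l1)) / scale, 1e-6)
    expect_lt(max(abs(eig$l2 - orc$l2)) / scale, 1e-6)
  }
})

test_that("frangi matches the oracle on random images and is in [0,1]", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(64 * 64), 64)
    p <- vesselness_params(kernel_px = 3)
    v <- frangi(m, p)$values
    expect_true(all(v >= 0 & v <= 1))
    expect_lt(max(abs(v - oracle_frangi(m, p))), 1e-6)
  }
})

test_that("additive offsets and (adaptive) gains do not change frangi", {
  set.seed(12)
  m <- matrix(runif(48 * 48), 48)
  p <- vesselness_params(kernel_px = 5)
  v0 <- frangi(m, p)$values
  expect_lt(max(abs(frangi(m + 100, p)$values - v0)), 1e-9)
  v_gain <- frangi(3.7 * m, p)$values
  expect_lt(max(abs(v_gain - v0)), 1e-6)
})

test_that("a scale-matched ridge responds strongest on its centerline", {
  n <- 96
  img <- matrix(0, n, n)
  img[abs(seq_len(n) - n / 2) <= 2, ] <- 1   # horizontal ridge ~ 5 px
  img <- gaussian_smooth(img, 1)
  v <- frangi(img, vesselness_params(kernel_px = 5))$values
  center <- v[n / 2, n / 2]
  off <- v[n / 2 + 12, n / 2]    # >= 2x width lateral offset
  expect_gt(center, off)
  expect_gt(center, 0.5)
})

test_that("vesselness is approximately rotation-equivariant", {
  # ridge at 30 degrees vs rotated response of an axis-aligned ridge
  n <- 121
  mk <- function(theta) {
    x <- matrix(rep(seq_len(n) - (n + 1) / 2, each = n), n)
    y <- t(x)
    d <- abs(x * sin(theta) - y * cos(theta))
    exp(-d^2 / (2 * 4^2))
  }
  p <- vesselness_params(kernel_px = 8, c_mode = "fixed", c_value = 1)
  v0 <- frangi(mk(0), p)$values
  v30 <- frangi(mk(pi / 6), p)$values
  c0 <- (n + 1) / 2
  core <- 30:(n - 30)
  # peak response is orientation-independent to 5%
  expect_lt(abs(max(v30[core, core]) / max(v0[core, core]) - 1), 0.05)
  # centerline response along the rotated ridge matches the axial one:
  # sample v30 on the ridge line y = x / tan(60deg) through the center
  # ridge line of mk(theta): row - c0 = (col - c0) * tan(theta)
  on_ridge <- vapply(core - c0, function(s) {
    v30[round(c0 + s * sin(pi / 6)), round(c0 + s * cos(pi / 6))]
  }, numeric(1))
  expect_lt(abs(mean(on_ridge) / mean(v0[c0, core]) - 1), 0.05)
  # far off-ridge (>= 2x width) both orientations are quiet
  perp <- abs((col(v30) - c0) * sin(pi / 6) - (row(v30) - c0) * cos(pi / 6))
  far <- perp > 16 & row(v30) %in% core & col(v30) %in% core
  expect_lt(max(v30[far]), 0.1 * max(v0))
})

test_that("parameter validation rejects bad vesselness settings", {
  expect_error(vesselness_params(kernel_px = 0), "kernel_px")
  expect_error(vesselness_params(beta = 0), "beta")
  expect_error(vesselness_params(c_mode = "fixed"), "c_value")
})
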