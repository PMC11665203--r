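# Skeletonization, the segment graph, diameters, VLD and the ESF.

clean_spec <- function(seed = 2)
  phantom_spec(n_trees = 0, psf_fwhm_um = 0, noise_sigma = 0, seed = seed)

fake_graph <- function(lengths_um, diam_um, area_mm2 = 4) {
  structure(list(
    segments = data.frame(id = seq_along(lengths_um),
                          length_um = lengths_um,
                          mean_diameter_um = diam_um,
                          n_px = rep(10L, length(lengths_um))),
    paths = list(), n_nodes = 0L, image_area_mm2 = area_mm2,
    pixel_pitch_um = 2000 / 512), class = "vessel_graph")
}

test_that("skeletonize_mask thins to the midline and stays inside", {
  expect_false(any(skeletonize_mask(matrix(FALSE, 10, 10))))
  bar <- matrix(FALSE, 40, 220)
  bar[16:25, 11:210] <- TRUE     # 10 px wide, 200 px long
  sk <- skeletonize_mask(bar)
  expect_true(all(bar[sk]))
  ri <- which(sk, arr.ind = TRUE)
  core <- ri[ri[, 2] > 25 & ri[, 2] < 195, ]
  expect_true(all(abs(core[, 1] - 20.5) <= 1.6))
  expect_gt(sum(sk), 180)
  # solid disk degenerates to a short central remnant
  n <- 81
  xy <- expand.grid(1:n, 1:n)
  disk <- matrix((xy[, 1] - 41)^2 + (xy[, 2] - 41)^2 <= 20^2, n)
  expect_lt(sum(skeletonize_mask(disk)), 40)
})

test_that("straight tubes recover length to 2 px and diameter to 1 px", {
  pitch <- 2000 / 512
  for (ang in c(0, 30, 45, 70)) {
    ph <- render_phantom(straight_vessel(1000, 20, ang), clean_spec())
    sk <- skeletonize_mask(ph$truth$mask)
    g <- build_graph(sk, ph$truth$mask, pitch)
    expect_equal(nrow(g$segments), 1L)
    expect_lt(abs(sum(g$segments$length_um) - 1000), 2 * pitch)
    expect_lt(abs(g$segments$mean_diameter_um[1] - 20), pitch)
  }
})

test_that("a symmetric Y junction yields 3 segments and 1 branch node", {
  c0 <- 1000
  mk <- function(ang) {
    t <- seq(0, 400, length.out = 100)
    list(points = cbind(x = c0 + t * cos(ang), y = c0 + t * sin(ang)),
         diameter_um = 20)
  }
  br <- list(mk(pi / 2), mk(pi / 2 + 2.1), mk(pi / 2 - 2.1))
  ph <- render_phantom(br, clean_spec())
  sk <- skeletonize_mask(ph$truth$mask)
  g <- build_graph(sk, ph$truth$mask, 2000 / 512)
  expect_equal(nrow(g$segments), 3L)
  expect_equal(g$n_nodes, 1L)
})

test_that("empty masks produce empty graphs and all-zero profiles", {
  g <- build_graph(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8), 4)
  expect_equal(nrow(g$segments), 0L)
  v <- vld_profile(g)
  expect_true(all(v$profile$vld == 0))
  expect_equal(v$total_vld, 0)
})

test_that("vld_profile arithmetic, bin-edge convention and invariants", {
  # 1000 um at 15 um diameter on 4 mm^2 -> 0.25 mm/mm^2 in (10,20)
  v <- vld_profile(fake_graph(1000, 15))
  expect_equal(v$profile$vld[2], 0.25)
  expect_equal(sum(v$profile$vld[-2]), 0)
  # a diameter exactly on an edge goes to the upper bin
  v10 <- vld_profile(fake_graph(500, 10))
  expect_equal(v10$profile$vld[2], 0.125)
  expect_equal(v10$profile$vld[1], 0)
  # total equals the bin sum
  set.seed(40)
  vr <- vld_profile(fake_graph(runif(20, 100, 900), runif(20, 3, 80)))
  expect_equal(sum(vr$profile$vld), vr$total_vld, tolerance = 1e-9)
})

test_that("adding a vessel never decreases total VLD", {
  spec <- clean_spec()
  two <- c(straight_vessel(800, 15, 0),
           lapply(straight_vessel(700, 25, 90), function(b) {
             b$points[, 1] <- b$points[, 1] + 400; b
           }))
  three <- c(two, lapply(straight_vessel(600, 40, 45), function(b) {
    b$points[, 1] <- b$points[, 1] - 550; b
  }))
  vld_of <- function(br) {
    ph <- render_phantom(br, spec)
    g <- build_graph(skeletonize_mask(ph$truth$mask), ph$truth$mask,
                     2000 / 512)
    vld_profile(g)$total_vld
  }
  expect_gt(vld_of(three), vld_of(two) - 1e-9)
})

test_that("the 8 um PSF biases sub-resolution diameters upward", {
  # the global-threshold map of a blurred capillary includes the blur
  # halo, so the apparent diameter exceeds the true one
  spec <- phantom_spec(n_trees = 0, psf_fwhm_um = 8, noise_sigma = 0,
                       seed = 3)
  ph <- render_phantom(straight_vessel(1200, 7, 20), spec)
  w <- equalize(ph$image)
  m1 <- map1_global(w, estimate_background(w))
  g <- build_graph(skeletonize_mask(m1), m1$mask, 2000 / 512)
  seg <- g$segments
  main <- seg[which.max(seg$length_um), ]
  expect_gte(main$mean_diameter_um, 7)
})

test_that("measure_esf matches the Gaussian closed form within 2%", {
  for (s in c(2, 3.4, 6)) {
    f <- measure_esf(synthetic_edge_image(s))
    expect_equal(f, 2 * sqrt(2 * log(2)) * s, tolerance = 0.02)
  }
  # sigma = 3.397 um -> the instrument's 8 um figure
  expect_equal(measure_esf(synthetic_edge_image(3.397)), 8.0,
               tolerance = 0.02 * 8)
  # doubling sigma doubles the FWHM
  f1 <- measure_esf(synthetic_edge_image(3))
  f2 <- measure_esf(synthetic_edge_image(6))
  expect_equal(f2 / f1, 2, tolerance = 0.02)
  # discretization floor for an ideal step
  pitch <- 2000 / 512
  expect_lte(measure_esf(synthetic_edge_image(0)), 1.5 * pitch)
  # horizontal edges work via the axis descriptor
  img <- synthetic_edge_image(4)
  timg <- intensity_image(t(img$pixels), img$pixel_pitch_um)
  expect_equal(measure_esf(timg, list(axis = "y")),
               measure_esf(img), tolerance = 1e-9)
})

test_that("measure_esf rejects profiles that are not a clean edge", {
  n <- 64
  ridge <- matrix(exp(-(seq_len(n) - 32)^2 / 18), n, n, byrow = TRUE)
  img <- intensity_image(ridge, 2000 / 512)
  expect_error(measure_esf(img), "non-monotone")
  expect_error(measure_esf(intensity_image(matrix(1, 8, 8))), "flat")
})
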