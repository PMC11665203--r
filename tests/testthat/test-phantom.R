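# Synthetic phantom generator: ground truth, determinism, noise model,
# plaque fields, cohorts.

test_that("an empty scene renders background only", {
  spec <- phantom_spec(n_trees = 0, noise_sigma = 0, background_level = 50,
                       seed = 1)
  ph <- generate_vessel_phantom(spec)
  expect_true(all(ph$image$pixels == 50))
  expect_length(ph$truth$centerlines, 0)
  expect_equal(unname(sum(ph$truth$per_bin_length_um)), 0)
  expect_false(any(ph$truth$mask))
})

test_that("a constructed straight vessel books its exact length in-bin", {
  spec <- phantom_spec(n_trees = 0, psf_fwhm_um = 0, noise_sigma = 0,
                       seed = 1)
  ph <- render_phantom(straight_vessel(1000, 15, 10), spec)
  pb <- ph$truth$per_bin_length_um
  expect_equal(unname(pb[["10-20"]]), 1000, tolerance = 1e-9)
  expect_equal(unname(sum(pb)), 1000, tolerance = 1e-9)
})

test_that("ground-truth lengths are conserved across bins", {
  for (sd in c(2, 9)) {
    ph <- generate_vessel_phantom(phantom_spec(seed = sd))
    expect_equal(unname(sum(ph$truth$per_bin_length_um)),
                 ph$truth$total_length_um, tolerance = 1e-6)
    expect_gt(ph$truth$total_length_um, 0)
  }
})

test_that("seeding is reproducible and sub-streams are independent", {
  spec <- phantom_spec(n_trees = 3, seed = 42)
  a <- generate_vessel_phantom(spec)
  b <- generate_vessel_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$centerlines, b$truth$centerlines)
  # a different seed changes the noise field
  spec2 <- spec; spec2$seed <- 43
  c3 <- generate_vessel_phantom(spec2)
  expect_false(identical(a$image$pixels, c3$image$pixels))
  # blur does not move centerlines: geometry identical with psf 0 vs 8
  s0 <- phantom_spec(n_trees = 3, psf_fwhm_um = 0, seed = 42)
  s8 <- phantom_spec(n_trees = 3, psf_fwhm_um = 8, seed = 42)
  expect_identical(generate_vessel_phantom(s0)$truth$centerlines,
                   generate_vessel_phantom(s8)$truth$centerlines)
})

test_that("background noise has the stated moments", {
  n <- 512
  spec <- phantom_spec(n_trees = 0, noise_sigma = 0.05,
                       background_level = 1, noise_corr_um = 0, seed = 6)
  px <- generate_vessel_phantom(spec)$image$pixels
  expect_lt(abs(mean(px) - 1), 3 * 0.05 / n)
  expect_lt(abs(sd(px) - 0.05), 3 * 0.05 / sqrt(2 * n^2))
  # bandlimited noise keeps the marginal s.d. by construction
  specc <- phantom_spec(n_trees = 0, noise_sigma = 0.05,
                        background_level = 1, noise_corr_um = 8, seed = 6)
  pxc <- generate_vessel_phantom(specc)$image$pixels
  expect_equal(sd(pxc), 0.05, tolerance = 0.01)
})

test_that("an unrenderable diameter is rejected with a diagnostic", {
  spec <- phantom_spec(n_trees = 0, seed = 1)
  expect_error(render_phantom(straight_vessel(500, 2), spec),
               "2.*unrenderable|unrenderable")
})

test_that("the diameter range and capillary fraction are honoured", {
  spec <- phantom_spec(seed = 4)   # defaults: 110 um roots, decay 0.6
  ph <- generate_vessel_phantom(spec)
  d <- vapply(ph$truth$centerlines, function(b) b$diameter_um, numeric(1))
  len <- vapply(ph$truth$centerlines, function(b)
    pamvasc:::.polyline_length(b$points), numeric(1))
  expect_gt(max(d), 80)         # large pial trunks
  expect_lt(min(d), 10)         # capillaries
  expect_gt(sum(len[d < 10]) / sum(len), 0.2)  # near the 0.3 target
})

test_that("plaque phantoms respect count, separation and determinism", {
  pp <- generate_plaque_phantom(0, 15, "flat", seed = 2)
  expect_equal(nrow(pp$truth$plaque_xy), 0L)
  pp25 <- generate_plaque_phantom(25, 15, "flat", seed = 2)
  xy <- pp25$truth$plaque_xy
  expect_equal(nrow(xy), 25L)
  expect_true(all(xy >= 0 & xy <= 2000))
  dd <- as.matrix(dist(xy))
  expect_gte(min(dd[upper.tri(dd)]), 3 * 15)
  expect_identical(generate_plaque_phantom(25, 15, "flat", seed = 2)
                   $truth$plaque_xy, xy)
  expect_error(generate_plaque_phantom(2000, 15, "flat", seed = 1),
               "cannot place")
})

test_that("simulate_cohort scales true per-bin VLD by the multiplier", {
  base <- phantom_spec(seed = 1)
  groups <- list(
    list(label = "WT", vld_multiplier_per_bin = 1,
         plaque_density_per_mm2 = 0),
    list(label = "AD", vld_multiplier_per_bin = c(1, 0.8, 1, 1, 1, 1),
         plaque_density_per_mm2 = 0))
  ratios <- vapply(1:20, function(r) {
    subs <- simulate_cohort(cohort_spec(2, groups, seed = 100 + r),
                            base, render = FALSE)
    lab <- vapply(subs, `[[`, "", "label")
    tv <- t(vapply(subs, function(s) truth_vld(s$truth, 4), numeric(6)))
    mean(tv[lab == "AD", 2]) / mean(tv[lab == "WT", 2])
  }, numeric(1))
  expect_equal(mean(ratios), 0.8, tolerance = 0.07)
  # exactly n_per_group phantoms per group, null design balanced
  subs <- simulate_cohort(cohort_spec(5, groups, seed = 3), base,
                          render = FALSE)
  expect_equal(as.integer(table(vapply(subs, `[[`, "", "label"))),
               c(5L, 5L))
})

test_that("cohort_spec validates its inputs", {
  expect_error(cohort_spec(1), "n_per_group")
  expect_error(cohort_spec(3, list(list(label = "A",
                                        vld_multiplier_per_bin = -1,
                                        plaque_density_per_mm2 = 0))))
})
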