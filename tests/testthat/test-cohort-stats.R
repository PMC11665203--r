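# Pooled two-sample t-test and cohort comparison report.

test_that("pooled t matches the hand-evaluated formula", {
  # a = (1,2,3), b = (2,3,4): pooled s^2 = 1, t = -1/sqrt(2/3)
  ct <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ct$t_statistic, -1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(round(ct$t_statistic, 4), -1.2247)
  expect_equal(ct$df, 4)
  expect_equal(ct$p_value, 2 * pt(-abs(ct$t_statistic), 4))
})

test_that("degenerate and symmetric cases behave as documented", {
  a <- c(5, 5, 5)
  expect_equal(unpaired_t_test(a, a)$t_statistic, 0)
  expect_equal(unpaired_t_test(a, a)$p_value, 1)
  expect_error(unpaired_t_test(c(5, 5), c(6, 6)), "zero pooled variance")
  set.seed(30)
  x <- rnorm(8); y <- rnorm(6, 1)
  f <- unpaired_t_test(x, y); r <- unpaired_t_test(y, x)
  expect_equal(f$t_statistic, -r$t_statistic)
  expect_equal(f$p_value, r$p_value)
  expect_error(unpaired_t_test(1, c(1, 2)), ">= 2")
  # agreement with stats::t.test(var.equal = TRUE)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(f$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(f$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("welch variant matches stats::t.test", {
  set.seed(31)
  x <- rnorm(9, sd = 1); y <- rnorm(14, sd = 3)
  got <- unpaired_t_test(x, y, welch = TRUE)
  ref <- t.test(x, y)
  expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
})

make_profile <- function(vals) {
  bins <- default_bins_um()
  profile <- data.frame(bin = pamvasc:::.bin_labels(bins),
                        lo_um = bins[-length(bins)], hi_um = bins[-1],
                        length_mm = vals * 4, vld = vals)
  structure(list(profile = profile, total_vld = sum(vals), area_mm2 = 4,
                 bins_um = bins), class = "vld_profile")
}

test_that("compare_cohort reports one row per metric and recomputes stats", {
  set.seed(32)
  labels <- rep(c("WT", "AD"), each = 4)
  vld <- lapply(seq_along(labels), function(i)
    make_profile(abs(rnorm(6, mean = if (labels[i] == "WT") 2 else 1.5))))
  plq <- c(rnorm(4, 2), rnorm(4, 8))
  rep_df <- compare_cohort(vld, labels, plaque_density = plq)
  expect_equal(nrow(rep_df), 6 + 1 + 1)  # bins + total + plaque
  r1 <- rep_df[rep_df$metric == "plaque_density", ]
  expect_equal(r1$mean_a, mean(plq[1:4]), tolerance = 1e-12)
  expect_equal(r1$sd_b, sd(plq[5:8]), tolerance = 1e-12)
  expect_equal(r1$se_a, sd(plq[1:4]) / 2, tolerance = 1e-12)
  expect_true(all(rep_df$p >= 0 & rep_df$p <= 1))
  expect_true(all(rep_df$p_holm >= rep_df$p))
  # identical subject lists -> p = 1 everywhere
  same <- compare_cohort(vld[c(1:4, 1:4)], labels)
  expect_true(all(same$p == 1))
  # group with n < 2 is skipped with a warning per metric
  w <- capture_warnings(sm <- compare_cohort(vld[1:5],
                                             c(rep("WT", 4), "AD")))
  expect_true(all(grepl("n < 2", w)))
  expect_gt(length(w), 0)
  expect_null(sm)
})

test_that("type-I error is calibrated and power ranks effects correctly", {
  # truth-level Monte Carlo on the t machinery with phantom-like spread
  set.seed(33)
  reps <- 100
  hits <- 0
  for (r in seq_len(reps)) {
    p <- unpaired_t_test(rnorm(5, 2, 0.3), rnorm(5, 2, 0.3))$p_value
    hits <- hits + (p < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(hits / reps - 0.05), 3 * se + 1e-9)
  # monotone power in effect size
  pow <- vapply(c(0.9, 0.7), function(mult) {
    mean(vapply(seq_len(60), function(r)
      unpaired_t_test(rnorm(5, 2, 0.15), rnorm(5, 2 * mult, 0.15))$p_value,
      numeric(1)) < 0.05)
  }, numeric(1))
  expect_gt(pow[2], pow[1])
})
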