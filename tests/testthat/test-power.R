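test_that("closed-form sample size matches the normal-approximation formula", {
  expect_equal(sample_size_per_arm(5.0, 5.0, 0.30), 175L)
  # unrounded oracle
  unrounded <- function(m, s, f, a = 0.05, p = 0.8)
    2 * (qnorm(1 - a / 2) + qnorm(p))^2 * s^2 / (f * m)^2
  for (f in c(0.2, 0.3, 0.4))
    expect_equal(sample_size_per_arm(4, 6, f),
                 as.integer(ceiling(unrounded(4, 6, f))))
  # doubling the SD quadruples the unrounded n
  expect_equal(unrounded(5, 10, 0.3), 4 * unrounded(5, 5, 0.3))
  # monotone in the effect; depends only on the coefficient of variation
  expect_lt(sample_size_per_arm(5, 5, 0.4), sample_size_per_arm(5, 5, 0.2))
  expect_equal(sample_size_per_arm(5, 5, 0.3),
               sample_size_per_arm(10, 10, 0.3))
  expect_error(sample_size_per_arm(-1, 5, 0.3), "positive")
  expect_error(sample_size_per_arm(5, 5, 1.5), "effect_fraction")
})

test_that("closed form agrees with an independent simulation oracle on a
           grid of designs", {
  for (sd in c(2.5, 5, 7.5)) {
    for (f in c(0.2, 0.3, 0.4)) {
      n <- sample_size_per_arm(5, sd, f)
      pow <- empirical_power(n, 5, sd, f, n_trials = 4000,
                             seed = round(sd * 100 + f * 10))
      expect_gt(pow, 0.765)
      expect_lt(pow, 0.845)
    }
  }
})

test_that("sample-size reductions follow the sign convention", {
  expect_equal(sample_size_reduction(200, 80), 60)
  expect_equal(sample_size_reduction(120, 120), 0)
  expect_equal(sample_size_reduction(200, 250), -25)
  expect_error(sample_size_reduction(1, 50), ">= 2")
})

test_that("bootstrap comparison flags separated groups, not identical ones", {
  set.seed(55)
  x <- rnorm(50, 1, 0.1)
  same <- bootstrap_compare(x, x, seed = 1)
  expect_false(same$significant)
  expect_equal(same$n_boot, 1000L)

  y <- rnorm(50, 2, 0.1)
  apart <- bootstrap_compare(x, y, seed = 1)
  expect_true(apart$significant)
  expect_equal(apart$boot_p, 0)

  # deterministic given seed
  again <- bootstrap_compare(x, y, seed = 1)
  expect_identical(apart, again)
  expect_false(identical(apart$ci_a,
                         bootstrap_compare(x, y, seed = 2)$ci_a))
  expect_error(bootstrap_compare(x[1:5], y), "n >= 10")
  expect_warning(bootstrap_compare(x, y, n_boot = 50, seed = 1), "unstable")
})

test_that("clearly separated samples are significant across many seeds", {
  set.seed(77)
  hits <- vapply(1:25, function(i) {
    a <- rnorm(50, 1, 0.1)
    b <- rnorm(50, 2, 0.1)
    bootstrap_compare(a, b, seed = i)$significant
  }, logical(1))
  expect_true(all(hits))
})

test_that("reduction bootstrap recovers closed-form expectations", {
  set.seed(13)
  ref <- rnorm(80, 5, 2)
  # identical samples: exactly zero reduction in every paired replicate
  same <- bootstrap_sample_size_reduction(ref, ref, seed = 4)
  expect_equal(same$reduction_pct, 0)
  expect_equal(c(same$ci_low, same$ci_high), c(0, 0))
  expect_false(same$significant)

  # doubling the mean at equal sd scales n by 1/4 -> reduction near 75%
  roi <- ref + mean(ref)
  red <- bootstrap_sample_size_reduction(roi, ref, seed = 4)
  expect_gt(red$reduction_pct, 70)
  expect_lt(red$reduction_pct, 80)
  expect_true(red$significant)
  expect_gt(red$ci_low, 0)

  again <- bootstrap_sample_size_reduction(roi, ref, seed = 4)
  expect_identical(unclass(red), unclass(again))
})

test_that("replicates with nonpositive resampled means are redrawn", {
  set.seed(23)
  # mean barely positive: some resamples dip below zero and must be redrawn
  x <- c(rnorm(30, 0.4, 1.5))
  ref <- rnorm(30, 5, 1)
  res <- bootstrap_sample_size_reduction(x, ref, n_boot = 500, seed = 9)
  expect_gt(res$n_rejected, 0)
  expect_length(res$n_roi, 1)
})
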