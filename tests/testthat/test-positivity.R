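test_that("two-component EM recovers well-separated generating parameters", {
  set.seed(11)
  x <- c(rnorm(200, 1.20, 0.05), rnorm(100, 2.00, 0.30))
  fit <- fit_gmm_region(x, seed = 1)
  expect_false(fit$unimodal)
  expect_lt(abs(fit$mean_low - 1.20), 0.05)
  expect_lt(abs(fit$mean_high - 2.00), 0.05)
  expect_equal(fit$weight_low + fit$weight_high, 1, tolerance = 1e-9)

  # independent multi-restart EM oracle (mclust)
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(fit$mean_low - min(mc$parameters$mean)), 0.02)
  expect_lt(abs(fit$mean_high - max(mc$parameters$mean)), 0.02)
})

test_that("EM is deterministic given the seed", {
  set.seed(5)
  x <- c(rnorm(150, 1.2, 0.06), rnorm(80, 1.8, 0.2))
  f1 <- fit_gmm_region(x, seed = 42)
  f2 <- fit_gmm_region(x, seed = 42)
  expect_identical(f1[c("mean_low", "mean_high", "sd_low", "sd_high",
                        "weight_low", "cutoff")],
                   f2[c("mean_low", "mean_high", "sd_low", "sd_high",
                        "weight_low", "cutoff")])
})

test_that("degenerate and unimodal inputs are flagged", {
  expect_error(fit_gmm_region(rep(1.2, 10)), "at least 20")
  same <- fit_gmm_region(rep(1.2, 30))
  expect_true(same$unimodal)
  expect_identical(same$cutoff, Inf)

  set.seed(2)
  uni <- fit_gmm_region(rnorm(300, 1.20, 0.05), seed = 1)
  expect_true(uni$unimodal)
  expect_equal(positivity_probability(uni, c(1.0, 1.3, 2.5)), rep(0, 3))
})

test_that("positivity probability follows Bayes' rule and its cutoff", {
  mix <- tauroi:::new_region_mixture("r", 2 / 3, 1 / 3, 1.2, 2.0, 0.05, 0.3,
                                     NA, FALSE, NA, 300)
  mix$cutoff <- region_cutoff(mix, "posterior50")
  # hand oracle at suvr = 1.5
  num <- (1 / 3) * dnorm(1.5, 2.0, 0.3)
  den <- num + (2 / 3) * dnorm(1.5, 1.2, 0.05)
  expect_equal(positivity_probability(mix, 1.5), num / den,
               tolerance = 1e-12)
  expect_gt(positivity_probability(mix, 1.5), 0.999999)
  expect_equal(positivity_probability(mix, mix$cutoff), 0.5,
               tolerance = 1e-9)
  expect_error(positivity_probability(mix, -1), "positive")

  # posterior is nondecreasing in SUVR between the component means
  grid <- seq(mix$mean_low, mix$mean_high, length.out = 500)
  expect_true(all(diff(positivity_probability(mix, grid)) >= 0))
})

test_that("cutoff conventions match symmetry and arithmetic cases", {
  sym <- tauroi:::new_region_mixture("r", 0.5, 0.5, 1.0, 2.0, 0.1, 0.1,
                                     NA, FALSE, NA, 100)
  expect_equal(region_cutoff(sym, "posterior50"), 1.5, tolerance = 1e-9)

  low <- tauroi:::new_region_mixture("r", 0.6, 0.4, 1.20, 2.0, 0.05, 0.3,
                                     NA, FALSE, NA, 100)
  expect_equal(region_cutoff(low, "low_mean_plus_2sd"), 1.30)

  # dense-grid sign-change oracle
  post <- function(x) positivity_probability(low, x)
  g <- seq(1.2, 2.0, length.out = 200001)
  v <- post(g) - 0.5
  i <- which(v[-1] * v[-length(v)] <= 0)[1]
  expect_lt(abs(region_cutoff(low, "posterior50") - g[i]), 1e-5)

  set.seed(2)
  uni <- fit_gmm_region(rnorm(300, 1.20, 0.05), seed = 1)
  expect_warning(co <- region_cutoff(uni), "unimodal")
  expect_identical(co, Inf)
})

test_that("cutoff recovery across seeded replicates stays within 0.05 SUVR", {
  truth <- analytic_cutoff(2 / 3, 1.20, 0.05, 1 / 3, 2.00, 0.30)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- c(rnorm(200, 1.20, 0.05), rnorm(100, 2.00, 0.30))
    fit_gmm_region(x, seed = s)$cutoff - truth
  }, numeric(1))
  expect_true(all(abs(errs) < 0.05))
})

test_that("stage positivity thresholds volume-weighted stage means", {
  cat6 <- tiny_catalog(6)
  sets <- lapply(1:3, function(k)
    region_set(paste0("DDS_", k), sprintf("R%02d", (2 * k - 1):(2 * k)),
               stage_index = k))
  cutoffs <- c(DDS_1 = 1.3, DDS_2 = 1.3, DDS_3 = 1.3)
  suvr <- setNames(c(1.8, 1.8, 1.6, 1.6, 1.1, 1.1), sprintf("R%02d", 1:6))
  expect_equal(unname(stage_positivity(suvr, sets, cutoffs, cat6)),
               c(TRUE, TRUE, FALSE))
  expect_equal(unname(stage_positivity(suvr * 0.5, sets, cutoffs, cat6)),
               rep(FALSE, 3))
  expect_equal(unname(stage_positivity(suvr * 2, sets, cutoffs, cat6)),
               rep(TRUE, 3))
  expect_error(stage_positivity(suvr, sets, cutoffs[1:2], cat6),
               "missing cutoff")
})

test_that("mixture JSON serialization round-trips including Inf cutoffs", {
  set.seed(9)
  gen <- small_sim(seed = 9)
  mix <- fit_gmm_cohort(gen$cohort, level = "set",
                        sets = tauroi:::staged_sets_of(gen$region_sets))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_mixtures(mix, tmp)
  back <- read_mixtures(tmp)
  expect_equal(names(back), names(mix))
  for (nm in names(mix)) {
    expect_equal(back[[nm]]$mean_low, mix[[nm]]$mean_low)
    expect_equal(back[[nm]]$cutoff, mix[[nm]]$cutoff)
    expect_equal(back[[nm]]$unimodal, mix[[nm]]$unimodal)
  }
})
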