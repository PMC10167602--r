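test_that("simulation is fully deterministic under a fixed seed", {
  g1 <- small_sim(seed = 10)
  g2 <- small_sim(seed = 10)
  expect_identical(g1$cohort$baseline, g2$cohort$baseline)
  expect_identical(g1$cohort$followup, g2$cohort$followup)
  expect_identical(g1$cohort$subjects, g2$cohort$subjects)
  expect_identical(unclass(g1$connectivity), unclass(g2$connectivity))
  expect_identical(g1$ground_truth$stage, g2$ground_truth$stage)
  g3 <- small_sim(seed = 11)
  expect_false(identical(g1$cohort$baseline, g3$cohort$baseline))
})

test_that("connectivity template is modular with valid invariants", {
  conn <- simulate_connectivity(40, 5, seed = 2)
  expect_s3_class(conn, "connectivity_matrix")
  module <- ceiling(seq_len(40) * 5 / 40)
  same <- outer(module, module, "==") & upper.tri(conn)
  diff_mod <- (!outer(module, module, "==")) & upper.tri(conn)
  expect_gt(mean(conn[same]), mean(conn[diff_mod]))
  expect_identical(conn, simulate_connectivity(40, 5, seed = 2))
  expect_error(simulate_connectivity(10, 0), "module")
  expect_error(simulate_connectivity(10, 2, within_mean = 0.1,
                                     between_mean = 0.5), "within_mean")
})

test_that("zero rates and zero noise give identical scans", {
  cfg <- simulation_config(n_per_group = c(CU = 10, MCI = 5, AD = 5,
                                           controls = 5),
                           n_regions = 20, rate_max = 0, rate_sd = 0,
                           noise_sd = 0, seed = 4)
  gen <- simulate_cohort(cfg)
  expect_equal(gen$cohort$followup, gen$cohort$baseline, tolerance = 1e-12)
  tab <- change_table(gen$cohort, gen$region_sets["wholebrain_meta"])
  expect_equal(tab$annual_pct_change, rep(0, nrow(tab)), tolerance = 1e-10)
})

test_that("affected regions carry the configured positive shift", {
  gen <- small_sim(seed = 12)
  gt <- gen$ground_truth
  bl <- gen$cohort$baseline
  aff <- una <- numeric(0)
  for (sid in rownames(bl)) {
    rs <- gt$region_stage[sid, ]
    S <- gt$stage[sid]
    aff <- c(aff, bl[sid, rs >= 1 & rs <= S])
    una <- c(una, bl[sid, rs > S])
  }
  shift_mean <- unname(gt$config$positive_shift["mean"])
  expect_lt(abs((mean(aff) - mean(una)) - shift_mean), 0.05)
})

test_that("controls are tau-free and stage draws follow the group mix", {
  gen <- small_sim(seed = 13)
  gt <- gen$ground_truth
  ctrl <- is_control(gen$cohort)
  expect_true(all(gt$stage[ctrl] == 0))
  expect_true(all(gt$stage[!ctrl] %in% 0:5))
  # rates peak in the most recently attained stage
  for (sid in names(gt$stage)[gt$stage > 0][1:10]) {
    S <- gt$stage[sid]
    rs <- gt$region_stage[sid, ]
    most_recent <- mean(gt$rates[sid, rs == S])
    other <- gt$rates[sid, rs < S & rs >= 1]
    if (length(other)) expect_gte(most_recent, mean(other))
    expect_true(all(gt$rates[sid, rs > S] == 0))
  }
})

test_that("epicenter heterogeneity zero gives one shared epicenter", {
  cfg <- simulation_config(n_per_group = c(CU = 8, MCI = 4, AD = 4,
                                           controls = 4),
                           n_regions = 20, epicenter_heterogeneity = 0,
                           seed = 5)
  gen <- simulate_cohort(cfg)
  epis <- unique(gen$ground_truth$epicenter)
  expect_length(epis, 1)
  expect_setequal(epis[[1]], gen$region_sets$DDS_1$region_ids)

  het <- simulate_cohort(simulation_config(
    n_per_group = c(CU = 20, MCI = 4, AD = 4, controls = 4),
    n_regions = 20, epicenter_heterogeneity = 0.8, seed = 5))
  expect_gt(length(unique(het$ground_truth$epicenter)), 1)
  # swaps preserve the number of stage-1 regions per subject
  n_stage1 <- rowSums(het$ground_truth$region_stage == 1)
  expect_true(all(n_stage1 == length(het$region_sets$DDS_1$region_ids)))
})

test_that("voxel blocks match the regional scans they were drawn from", {
  cfg <- simulation_config(n_per_group = c(CU = 4, MCI = 2, AD = 2,
                                           controls = 2),
                           n_regions = 10, voxels_per_region = 50,
                           voxel_sd = 0.02, seed = 6)
  gen <- simulate_cohort(cfg)
  vb <- gen$voxel_blocks[[1]]$baseline
  expect_equal(length(vb$voxel_suvr), 10 * 50)
  r <- gen$cohort$catalog$region_id[3]
  expect_lt(abs(mean(vb$voxel_suvr[vb$voxel_region == r]) -
                  gen$cohort$baseline[1, r]), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(stage_distribution = list(
    CU = c(0.5, 0.5), MCI = c(1, 0), AD = c(1, 0))), "n_stages")
  expect_error(simulation_config(epicenter_heterogeneity = 2), "\\[0, 1\\]")
  expect_error(simulation_config(n_regions = 5), "2 regions per stage")
})
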