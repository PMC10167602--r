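#' Configuration for the synthetic longitudinal tau-PET cohort
#'
#' Encodes the statistical structure the analysis assumes: a two-component
#' (tau-negative / tau-positive) regional SUVR distribution, hierarchical
#' stage-wise spread with subject-specific epicenters, accumulation rates
#' that peak in the most recently affected stage, diagnostic groups
#' differing only in their attained-stage distribution, a roughly 1.8-year
#' scan interval with measurement noise, and a modular connectivity template
#' aligned with the staged spreading pattern. An amyloid-negative control
#' group carries no tau-positive regions.
#'
#' @param n_per_group named integer vector: subjects per group
#'   (CU, MCI, AD, controls).
#' @param n_regions number of cortical regions.
#' @param n_stages number of ordered data-driven stages (regions are
#'   partitioned evenly into stages, which double as connectivity modules).
#' @param stage_distribution per group, probabilities over the attained
#'   stage 0..n_stages (0 = tau-free).
#' @param epicenter_heterogeneity probability in [0, 1] that each stage-1
#'   region is, for a given subject, swapped with a connectivity-neighbouring
#'   region from a later stage (0 = every subject shares the template
#'   epicenter).
#' @param base_suvr c(mean, sd) of the tau-negative regional SUVR.
#' @param positive_shift c(mean, sd) of the SUVR elevation in affected
#'   regions.
#' @param rate_max mean annual percentage accumulation in each subject's
#'   most recently attained stage.
#' @param recency_gradient multiplicative decay of the rate per step back in
#'   the stage cascade (rate of stage k for a subject at stage S has mean
#'   rate_max * recency_gradient^(S - k)).
#' @param rate_sd between-subject SD of the stage rates (%/y).
#' @param interval_years c(mean, sd) of the scan interval (floored at 0.5 y).
#' @param noise_sd SUVR measurement noise SD per region and timepoint.
#' @param voxels_per_region voxels simulated per region (0 disables voxel
#'   blocks).
#' @param voxel_sd SD of voxel SUVR around the regional value.
#' @param within_mean,between_mean,conn_jitter_sd connectivity template
#'   parameters (within-module vs between-module mean weight and jitter).
#' @param seed integer seed; the full output is deterministic given it.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(
    n_per_group = c(CU = 97, MCI = 77, AD = 41, controls = 69),
    n_regions = 200L,
    n_stages = 5L,
    stage_distribution = list(
      CU  = c(0.15, 0.30, 0.25, 0.15, 0.10, 0.05),
      MCI = c(0.05, 0.10, 0.20, 0.30, 0.20, 0.15),
      AD  = c(0.00, 0.05, 0.10, 0.20, 0.30, 0.35)),
    epicenter_heterogeneity = 0.3,
    base_suvr = c(mean = 1.20, sd = 0.05),
    positive_shift = c(mean = 0.60, sd = 0.20),
    rate_max = 8,
    recency_gradient = 0.5,
    rate_sd = 2,
    interval_years = c(mean = 1.8, sd = 0.3),
    noise_sd = 0.03,
    voxels_per_region = 0L,
    voxel_sd = 0.15,
    within_mean = 0.6,
    between_mean = 0.15,
    conn_jitter_sd = 0.05,
    seed = 1L) {
  cfg <- as.list(environment())
  if (!all(c("CU", "MCI", "AD", "controls") %in% names(cfg$n_per_group)))
    stop("n_per_group must name CU, MCI, AD, controls")
  for (g in c("CU", "MCI", "AD")) {
    p <- cfg$stage_distribution[[g]]
    if (length(p) != cfg$n_stages + 1L)
      stop("stage_distribution$", g, " must have n_stages + 1 entries ",
           "(attained stage 0..n_stages)")
    if (abs(sum(p) - 1) > 1e-9)
      stop("stage_distribution$", g, " must sum to 1")
  }
  if (cfg$epicenter_heterogeneity < 0 || cfg$epicenter_heterogeneity > 1)
    stop("epicenter_heterogeneity must lie in [0, 1]")
  if (cfg$n_regions < 2L * cfg$n_stages)
    stop("need at least 2 regions per stage")
  structure(cfg, class = "simulation_config")
}

sim_region_ids <- function(n_regions) {
  sprintf("R%0*d", nchar(as.character(n_regions)), seq_len(n_regions))
}

#' Simulate a modular connectivity template
#'
#' Block-modular symmetric weight matrix: weights are Gaussian around
#' \code{within_mean} inside a module and \code{between_mean} across
#' modules, clipped to (0, 1], with unit diagonal. Stands in for a
#' functional-connectivity template averaged over amyloid-negative
#' controls.
#'
#' @param n_regions,n_modules matrix size and number of modules (regions
#'   are assigned to modules in contiguous blocks).
#' @param within_mean,between_mean mean weight within / between modules
#'   (within must exceed between, both > 0).
#' @param jitter_sd Gaussian jitter SD.
#' @param seed integer seed.
#' @param region_ids optional region ids (defaults to R001..).
#' @return a \code{\link{connectivity_matrix}}.
#' @export
simulate_connectivity <- function(n_regions, n_modules,
                                  within_mean = 0.6, between_mean = 0.15,
                                  jitter_sd = 0.05, seed = 1L,
                                  region_ids = NULL) {
  if (n_modules < 1L || n_modules > n_regions)
    stop("simulate_connectivity: invalid module count")
  if (!(within_mean > between_mean && between_mean > 0))
    stop("simulate_connectivity: need within_mean > between_mean > 0")
  if (is.null(region_ids)) region_ids <- sim_region_ids(n_regions)
  module <- ceiling(seq_len(n_regions) * n_modules / n_regions)
  w <- withr_seed(seed, {
    same <- outer(module, module, "==")
    mu <- ifelse(same, within_mean, between_mean)
    jit <- matrix(stats::rnorm(n_regions^2, 0, jitter_sd), n_regions)
    m <- mu + jit
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m <- pmin(pmax(m, 0.01), 1)
    diag(m) <- 1
    m
  })
  dimnames(w) <- list(region_ids, region_ids)
  connectivity_matrix(w)
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' Generates, deterministically under the config seed: a region catalog, a
#' modular connectivity template, staged region sets (DDS_1..DDS_K plus
#' temporal and whole-brain meta-ROIs, where the temporal meta-ROI is the
#' union of the first three stages), and a two-timepoint cohort. Per
#' subject, an attained stage is drawn from the group's stage distribution;
#' regions at or below that stage carry a tau-positive SUVR shift at
#' baseline and accumulate fastest in the most recently attained stage.
#' Measurement noise is added to each scan. Controls (amyloid-negative CU)
#' are tau-free.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{cohort} (a \code{\link{tau_cohort}}),
#'   \code{region_sets}, \code{connectivity}, \code{voxel_blocks} (or NULL),
#'   and \code{ground_truth} (subject stages, per-subject region stage map,
#'   per-subject regional rates in %/y, subject-specific epicenters, config).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n_regions <- config$n_regions
  K <- config$n_stages
  region_ids <- sim_region_ids(n_regions)
  tpl_stage <- ceiling(seq_len(n_regions) * K / n_regions)

  conn <- simulate_connectivity(n_regions, K, config$within_mean,
                                config$between_mean, config$conn_jitter_sd,
                                seed = config$seed, region_ids = region_ids)

  sets <- lapply(seq_len(K), function(k)
    region_set(paste0("DDS_", k), region_ids[tpl_stage == k],
               stage_index = k))
  names(sets) <- paste0("DDS_", seq_len(K))
  sets$temporal_meta <- region_set("temporal_meta",
                                   region_ids[tpl_stage <= min(3L, K)])
  sets$wholebrain_meta <- region_set("wholebrain_meta", region_ids)

  groups <- rep(c("CU", "MCI", "AD", "controls"),
                times = config$n_per_group[c("CU", "MCI", "AD", "controls")])
  n_subj <- length(groups)
  subject_ids <- sprintf("S%0*d", nchar(as.character(n_subj)),
                         seq_len(n_subj))

  out <- withr_seed(config$seed + 1L, {
    volume <- round(stats::runif(n_regions, 500, 2000))
    stage <- integer(n_subj)
    region_stage <- matrix(rep(tpl_stage, each = n_subj), n_subj, n_regions,
                           dimnames = list(subject_ids, region_ids))
    rates <- matrix(0, n_subj, n_regions,
                    dimnames = list(subject_ids, region_ids))
    bl <- fu <- matrix(NA_real_, n_subj, n_regions,
                       dimnames = list(subject_ids, region_ids))
    dt <- pmax(stats::rnorm(n_subj, config$interval_years["mean"],
                            config$interval_years["sd"]), 0.5)
    epicenter <- vector("list", n_subj)
    names(epicenter) <- subject_ids
    stage1_tpl <- which(tpl_stage == 1L)
    later_tpl <- which(tpl_stage != 1L)
    for (i in seq_len(n_subj)) {
      g <- groups[i]
      if (g == "controls") {
        stage[i] <- 0L
      } else {
        stage[i] <- sample(0:K, 1L, prob = config$stage_distribution[[g]])
      }
      # subject-specific epicenter: template stage-1 regions, each swapped
      # with its strongest non-stage-1 connectivity neighbour with
      # probability epicenter_heterogeneity
      rs <- tpl_stage
      if (config$epicenter_heterogeneity > 0) {
        swap <- stage1_tpl[stats::runif(length(stage1_tpl)) <
                             config$epicenter_heterogeneity]
        used <- integer(0)
        for (r in swap) {
          cand <- setdiff(later_tpl, used)
          partner <- cand[which.max(conn[r, cand])]
          tmp <- rs[r]; rs[r] <- rs[partner]; rs[partner] <- tmp
          used <- c(used, partner)
        }
      }
      region_stage[i, ] <- rs
      epicenter[[i]] <- region_ids[rs == 1L]
      S <- stage[i]
      affected <- rs >= 1L & rs <= S
      base <- stats::rnorm(n_regions, config$base_suvr["mean"],
                           config$base_suvr["sd"])
      shift <- pmax(stats::rnorm(n_regions, config$positive_shift["mean"],
                                 config$positive_shift["sd"]), 0)
      bl_true <- base + affected * shift
      if (S >= 1L) {
        stage_rate <- pmax(stats::rnorm(
          S, config$rate_max * config$recency_gradient^((S - 1):0),
          config$rate_sd), 0)
        rates[i, affected] <- stage_rate[rs[affected]]
      }
      fu_true <- bl_true * (1 + rates[i, ] * dt[i] / 100)
      bl[i, ] <- pmax(bl_true + stats::rnorm(n_regions, 0, config$noise_sd),
                      0.05)
      fu[i, ] <- pmax(fu_true + stats::rnorm(n_regions, 0, config$noise_sd),
                      0.05)
    }
    vbs <- NULL
    if (config$voxels_per_region > 0L) {
      vpr <- config$voxels_per_region
      vox_region <- rep(region_ids, each = vpr)
      vbs <- vector("list", n_subj)
      names(vbs) <- subject_ids
      for (i in seq_len(n_subj)) {
        mk <- function(suvr_row, tp) {
          vox <- pmax(stats::rnorm(n_regions * vpr,
                                   rep(suvr_row, each = vpr),
                                   config$voxel_sd), 0.05)
          voxel_block(subject_ids[i], tp, vox, vox_region)
        }
        vbs[[i]] <- list(baseline = mk(bl[i, ], "baseline"),
                         followup = mk(fu[i, ], "followup"))
      }
    }
    list(volume = volume, stage = stage, region_stage = region_stage,
         rates = rates, bl = bl, fu = fu, dt = dt, epicenter = epicenter,
         voxel_blocks = vbs)
  })

  catalog <- region_catalog(region_ids, volume = out$volume,
                            atlas_tag = "synthetic")
  subjects <- data.frame(
    subject_id = subject_ids,
    group = ifelse(groups == "controls", "CU", groups),
    abeta = ifelse(groups == "controls", "negative", "positive"),
    interval_years = out$dt, stringsAsFactors = FALSE)
  cohort <- tau_cohort(subjects, out$bl, out$fu, catalog)
  list(cohort = cohort,
       region_sets = validate_region_sets(sets, catalog),
       connectivity = conn,
       voxel_blocks = out$voxel_blocks,
       ground_truth = list(stage = stats::setNames(out$stage, subject_ids),
                           region_stage = out$region_stage,
                           rates = out$rates,
                           epicenter = out$epicenter,
                           config = config))
}

#' Build a synthetic subtype/stage model fixture
#'
#' Constructs a fixed event-sequence model: each subtype receives a disjoint,
#' seeded sample of regions; its event sequence visits those regions at
#' increasing z thresholds (one pass per threshold level), giving
#' n_stages = regions-per-subtype x length(z_levels) events with per-region
#' monotone thresholds and pairwise-distinct sequences across subtypes.
#'
#' @param region_ids available region identifiers.
#' @param n_subtypes number of subtypes (default 4).
#' @param n_stages events per sequence (default 30); must be a multiple of
#'   \code{length(z_levels)}.
#' @param z_levels increasing z thresholds of the event passes.
#' @param seed integer seed.
#' @return a \code{\link{sustain_model}}.
#' @export
make_sustain_model <- function(region_ids, n_subtypes = 4L, n_stages = 30L,
                               z_levels = c(1, 2, 3), seed = 1L) {
  if (n_stages %% length(z_levels) != 0L)
    stop("make_sustain_model: n_stages must be a multiple of ",
         "length(z_levels)")
  rps <- n_stages %/% length(z_levels)
  if (length(region_ids) < n_subtypes * rps)
    stop("make_sustain_model: need at least ", n_subtypes * rps,
         " regions for ", n_subtypes, " disjoint subtype trajectories")
  seqs <- withr_seed(seed, {
    pool <- sample(region_ids)
    lapply(seq_len(n_subtypes), function(s) {
      regs <- pool[((s - 1L) * rps + 1L):(s * rps)]
      data.frame(region_id = rep(regs, times = length(z_levels)),
                 z_threshold = rep(sort(z_levels), each = rps),
                 stringsAsFactors = FALSE)
    })
  })
  sustain_model(seqs)
}
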