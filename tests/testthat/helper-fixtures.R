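# shared fixtures and independent oracles, built in code at test time

tiny_catalog <- function(n = 6, volume = NULL) {
  ids <- sprintf("R%02d", seq_len(n))
  region_catalog(ids, volume = if (is.null(volume)) rep(1000, n) else volume)
}

# small seeded cohort for plumbing tests
small_sim <- function(seed = 1, ...) {
  cfg <- simulation_config(
    n_per_group = c(CU = 30, MCI = 25, AD = 20, controls = 25),
    n_regions = 40, seed = seed, ...)
  simulate_cohort(cfg)
}

# independent simulation oracle: empirical power of a two-arm two-sided
# t-test at n per arm, vectorized over trials
empirical_power <- function(n_per_arm, mean_change, sd_change,
                            effect_fraction, alpha = 0.05,
                            n_trials = 10000, seed = 1) {
  set.seed(seed)
  delta <- effect_fraction * mean_change
  placebo <- matrix(rnorm(n_per_arm * n_trials, mean_change, sd_change),
                    n_per_arm)
  treated <- matrix(rnorm(n_per_arm * n_trials, mean_change - delta,
                          sd_change), n_per_arm)
  m1 <- colMeans(placebo); m2 <- colMeans(treated)
  v1 <- colSums((placebo - rep(m1, each = n_per_arm))^2) / (n_per_arm - 1)
  v2 <- colSums((treated - rep(m2, each = n_per_arm))^2) / (n_per_arm - 1)
  se <- sqrt((v1 + v2) / n_per_arm)
  tstat <- (m1 - m2) / se
  df <- 2 * n_per_arm - 2
  mean(abs(tstat) > qt(1 - alpha / 2, df))
}

# analytic posterior-0.5 cutoff of a known generating mixture
analytic_cutoff <- function(w_low, mu_low, sd_low, w_high, mu_high,
                            sd_high) {
  post <- function(x) {
    hi <- w_high * dnorm(x, mu_high, sd_high)
    lo <- w_low * dnorm(x, mu_low, sd_low)
    hi / (hi + lo)
  }
  uniroot(function(x) post(x) - 0.5, c(mu_low, mu_high), tol = 1e-12)$root
}

# brute-force expected z-score pattern for an event-sequence model,
# independent of the package implementation
oracle_expected_z <- function(model, subtype, stage) {
  e <- setNames(rep(0, length(model$regions)), model$regions)
  if (stage >= 1) {
    sq <- model$event_sequences[[subtype]]
    for (i in seq_len(stage)) {
      r <- sq$region_id[i]
      e[r] <- max(e[r], sq$z_threshold[i])
    }
  }
  e
}
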