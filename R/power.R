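#' Sample size per arm for a two-arm trial on tau-PET change
#'
#' Number of participants per arm needed to detect a treatment effect that
#' reduces the mean annual change by \code{effect_fraction} relative to
#' placebo, for a two-sided two-sample comparison of means at significance
#' \code{alpha} and the given power. Uses the normal-approximation closed
#' form n = ceil(2 (z_{1-alpha/2} + z_{power})^2 sd^2 / (f mean)^2), which
#' depends on (mean, sd) only through the coefficient of variation sd/mean.
#'
#' @param mean_change positive group mean annual change (the placebo-arm
#'   expectation; power is undefined for non-accumulating groups).
#' @param sd_change positive SD of the annual change.
#' @param effect_fraction fractional reduction versus placebo, in (0, 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return integer sample size per arm.
#' @examples
#' sample_size_per_arm(5.0, 5.0, 0.30)  # 175
#' @export
sample_size_per_arm <- function(mean_change, sd_change, effect_fraction,
                                alpha = 0.05, power = 0.80) {
  if (!is.finite(mean_change) || mean_change <= 0)
    stop("sample_size_per_arm: mean change must be positive; ",
         "power is undefined for a non-accumulating group")
  if (sd_change <= 0) stop("sample_size_per_arm: sd must be positive")
  if (effect_fraction <= 0 || effect_fraction >= 1)
    stop("sample_size_per_arm: effect_fraction must lie in (0, 1)")
  delta <- effect_fraction * mean_change
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- ceiling(2 * z^2 * sd_change^2 / delta^2)
  if (n > .Machine$integer.max)
    stop("sample_size_per_arm: required n exceeds integer range; ",
         "the detectable effect is negligible relative to variability")
  as.integer(n)
}

#' Percentage sample-size reduction of one ROI versus a reference
#'
#' 100 * (1 - n_roi / n_reference); negative when the candidate ROI needs
#' more participants than the reference.
#'
#' @param n_reference,n_roi sample sizes per arm (each >= 2).
#' @return percent reduction.
#' @export
sample_size_reduction <- function(n_reference, n_roi) {
  if (n_reference < 2 || n_roi < 2)
    stop("sample_size_reduction: sample sizes must be >= 2")
  100 * (1 - n_roi / n_reference)
}

#' Bootstrap comparison of two groups of values
#'
#' Resamples each group with replacement \code{n_boot} times, computes the
#' statistic per replicate, and forms percentile 95% CIs per group. The
#' difference is called significant when the observed statistic of the
#' higher-valued group exceeds the upper bound of the lower-valued group's
#' CI. \code{boot_p} is the fraction of replicate pairs in which the
#' observed ordering reverses.
#'
#' @param values_a,values_b numeric samples (each n >= 10).
#' @param statistic_fn statistic computed per replicate (default mean).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param conf_level CI level.
#' @return list with \code{significant}, \code{boot_p}, \code{stat_a},
#'   \code{stat_b}, \code{ci_a}, \code{ci_b}, \code{n_boot}.
#' @export
bootstrap_compare <- function(values_a, values_b, statistic_fn = mean,
                              n_boot = 1000L, seed = 1L,
                              conf_level = 0.95) {
  if (length(values_a) < 10L || length(values_b) < 10L)
    stop("bootstrap_compare: each sample must have n >= 10")
  if (n_boot < 100L)
    warning("bootstrap_compare: n_boot < 100 gives unstable CIs")
  stat_a <- statistic_fn(values_a)
  stat_b <- statistic_fn(values_b)
  reps <- withr_seed(seed, {
    ra <- replicate(n_boot, statistic_fn(
      sample(values_a, replace = TRUE)))
    rb <- replicate(n_boot, statistic_fn(
      sample(values_b, replace = TRUE)))
    list(a = ra, b = rb)
  })
  pr <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci_a <- stats::quantile(reps$a, pr, names = FALSE, type = 7)
  ci_b <- stats::quantile(reps$b, pr, names = FALSE, type = 7)
  if (stat_a == stat_b) {
    significant <- FALSE
    boot_p <- mean(reps$a > reps$b)  # informational for exact ties
  } else if (stat_a > stat_b) {
    significant <- stat_a > ci_b[2]
    boot_p <- mean(reps$a < reps$b)
  } else {
    significant <- stat_b > ci_a[2]
    boot_p <- mean(reps$b < reps$a)
  }
  # degenerate constant samples: CI collapses to the constant
  list(significant = significant, boot_p = boot_p,
       stat_a = stat_a, stat_b = stat_b, ci_a = ci_a, ci_b = ci_b,
       n_boot = as.integer(n_boot))
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bootstrap CI on the sample-size reduction between two ROIs
#'
#' For paired change samples (the same subjects measured in a candidate ROI
#' and a reference ROI), resamples subjects with replacement; per replicate,
#' recomputes mean and SD of each ROI's changes, the per-arm sample sizes at
#' the given effect fraction, and the percentage reduction. Reports the
#' observed reduction, its percentile 95% CI and significance versus 0 (CI
#' excluding 0). Replicates in which either resampled mean is nonpositive
#' (power undefined) are rejected and redrawn, with the count reported.
#'
#' @param changes_roi,changes_ref per-subject annual changes in the
#'   candidate and reference ROI; equal length = paired resampling (same
#'   subjects), unequal = independent resampling.
#' @param effect_fraction fractional treatment effect.
#' @param alpha,power forwarded to \code{\link{sample_size_per_arm}}.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param max_redraw cap on rejected-replicate redraws (replicates whose
#'   resampled mean is nonpositive, or so close to zero that the required n
#'   is not representable, are redrawn).
#' @return list of class \code{power_result}: \code{n_roi}, \code{n_ref},
#'   \code{reduction_pct}, \code{ci_low}, \code{ci_high},
#'   \code{significant}, \code{boot_p} (fraction of replicates with
#'   reduction <= 0), \code{n_rejected}, plus the inputs echoed.
#' @export
bootstrap_sample_size_reduction <- function(changes_roi, changes_ref,
                                            effect_fraction = 0.30,
                                            alpha = 0.05, power = 0.80,
                                            n_boot = 1000L, seed = 1L,
                                            max_redraw = 10000L) {
  paired <- length(changes_roi) == length(changes_ref)
  n_calc <- function(x) sample_size_per_arm(mean(x), stats::sd(x),
                                            effect_fraction, alpha, power)
  obs_n_roi <- n_calc(changes_roi)
  obs_n_ref <- n_calc(changes_ref)
  obs_red <- sample_size_reduction(obs_n_ref, obs_n_roi)
  res <- withr_seed(seed, {
    reds <- numeric(n_boot)
    rejected <- 0L
    b <- 1L
    while (b <= n_boot) {
      if (rejected > max_redraw)
        stop("bootstrap_sample_size_reduction: too many rejected ",
             "replicates (nonpositive resampled mean)")
      if (paired) {
        idx <- sample.int(length(changes_roi), replace = TRUE)
        xr <- changes_roi[idx]; xf <- changes_ref[idx]
      } else {
        xr <- sample(changes_roi, replace = TRUE)
        xf <- sample(changes_ref, replace = TRUE)
      }
      if (mean(xr) <= 0 || mean(xf) <= 0) {
        rejected <- rejected + 1L
        next
      }
      red_b <- tryCatch(sample_size_reduction(n_calc(xf), n_calc(xr)),
                        error = function(e) NULL)
      if (is.null(red_b)) {  # resampled n overflowed: effect negligible
        rejected <- rejected + 1L
        next
      }
      reds[b] <- red_b
      b <- b + 1L
    }
    list(reds = reds, rejected = rejected)
  })
  ci <- stats::quantile(res$reds, c(0.025, 0.975), names = FALSE)
  structure(list(n_roi = obs_n_roi, n_ref = obs_n_ref,
                 reduction_pct = obs_red,
                 boot_mean_reduction = mean(res$reds),
                 ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0,
                 boot_p = mean(res$reds <= 0),
                 n_rejected = res$rejected,
                 effect_fraction = effect_fraction, alpha = alpha,
                 power = power, n_boot = as.integer(n_boot), seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "power_result: n/arm %d vs reference %d (effect %.0f%%)\n",
    x$n_roi, x$n_ref, 100 * x$effect_fraction))
  cat(sprintf("  reduction %.2f%% [%.2f, %.2f], %s\n", x$reduction_pct,
              x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
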