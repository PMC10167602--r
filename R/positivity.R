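#' Fit a two-component Gaussian mixture to regional SUVR values
#'
#' Models the across-participant distribution of a region's baseline SUVR as
#' a mixture of a tau-negative (low) and tau-positive (high) Gaussian
#' component, fitted by EM. Initialization is deterministic: the first
#' restart seeds the component means from the lowest and highest deciles of
#' the data; the remaining restarts jitter that start using a seeded RNG. The
#' best log-likelihood wins, ties resolved by the first restart reaching it.
#'
#' A region is flagged unimodal (no meaningful tau-positive component) when
#' either fitted weight falls below \code{min_weight}, the component means
#' are closer than the larger component SD, or the two-component fit fails
#' to beat a single Gaussian on BIC. Unimodal regions get cutoff \code{Inf}
#' and positivity probability 0.
#'
#' @param values numeric vector of SUVR values (>= 20 finite positive values).
#' @param region_id optional region label stored in the result.
#' @param seed integer seed controlling restart jitter.
#' @param n_restarts number of EM restarts (default 10).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param min_weight minimum component weight for a bimodal call.
#' @return list of class \code{region_mixture} with fields \code{region_id},
#'   \code{weight_low}, \code{weight_high}, \code{mean_low}, \code{mean_high},
#'   \code{sd_low}, \code{sd_high}, \code{cutoff} (posterior = 0.5 point, or
#'   \code{Inf}), \code{unimodal}, \code{loglik}, \code{n}.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 1.2, 0.05), rnorm(100, 2.0, 0.3))
#' fit_gmm_region(x)$cutoff
#' @export
fit_gmm_region <- function(values, region_id = NA_character_, seed = 1L,
                           n_restarts = 10L, max_iter = 500L, tol = 1e-8,
                           min_weight = 0.02) {
  values <- values[is.finite(values)]
  if (length(values) < 20L)
    stop("fit_gmm_region: need at least 20 finite values, got ",
         length(values))
  if (any(values <= 0)) stop("fit_gmm_region: SUVR values must be positive")
  n <- length(values)
  s_all <- stats::sd(values)
  if (s_all == 0) {
    return(new_region_mixture(region_id, 0.5, 0.5, values[1], values[1],
                              0, 0, Inf, TRUE, NA_real_, n))
  }
  q <- stats::quantile(values, c(0.1, 0.9), names = FALSE)
  base <- list(w = c(0.5, 0.5),
               mu = c(mean(values[values <= q[1]]),
                      mean(values[values >= q[2]])),
               sigma = rep(s_all, 2))
  rng <- local({ set.seed(seed); lapply(seq_len(max(0L, n_restarts - 1L)),
    function(i) list(mu_jit = stats::rnorm(2, 0, s_all / 2),
                     w1 = stats::runif(1, 0.1, 0.9),
                     sig_mul = stats::runif(2, 0.5, 1.5))) })
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- base
    if (r > 1L) {
      j <- rng[[r - 1L]]
      init$mu <- sort(base$mu + j$mu_jit)
      init$w <- c(j$w1, 1 - j$w1)
      init$sigma <- base$sigma * j$sig_mul
    }
    fit <- em_two_gaussian(values, init, max_iter, tol)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik + 1e-12))
      best <- fit
  }
  if (is.null(best)) stop("fit_gmm_region: EM failed to converge")
  ord <- order(best$mu)
  w <- best$w[ord]; mu <- best$mu[ord]; sigma <- best$sigma[ord]
  # bimodality call: reject tiny components and overlapping means, and
  # require the two-component model to beat a single Gaussian on BIC
  # (guards against spurious splits of a unimodal distribution)
  sd_mle <- sqrt(mean((values - mean(values))^2))
  ll1 <- sum(stats::dnorm(values, mean(values), sd_mle, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * best$loglik + 5 * log(n)
  unimodal <- min(w) < min_weight || (mu[2] - mu[1]) < max(sigma) ||
    bic2 >= bic1
  mix <- new_region_mixture(region_id, w[1], w[2], mu[1], mu[2],
                            sigma[1], sigma[2],
                            cutoff = Inf, unimodal = unimodal,
                            loglik = best$loglik, n = n)
  if (!unimodal) mix$cutoff <- posterior50_cutoff(mix)
  mix
}

new_region_mixture <- function(region_id, w1, w2, mu1, mu2, s1, s2, cutoff,
                               unimodal, loglik, n) {
  structure(list(region_id = region_id, weight_low = w1, weight_high = w2,
                 mean_low = mu1, mean_high = mu2, sd_low = s1, sd_high = s2,
                 cutoff = cutoff, unimodal = unimodal, loglik = loglik,
                 n = n),
            class = "region_mixture")
}

#' @export
print.region_mixture <- function(x, ...) {
  cat(sprintf(
    "region_mixture [%s]: %.3f N(%.3f, %.3f) + %.3f N(%.3f, %.3f)\n",
    x$region_id, x$weight_low, x$mean_low, x$sd_low,
    x$weight_high, x$mean_high, x$sd_high))
  cat(if (x$unimodal) "  unimodal (cutoff = Inf)\n"
      else sprintf("  cutoff (posterior = 0.5): %.4f\n", x$cutoff))
  invisible(x)
}

em_two_gaussian <- function(x, init, max_iter, tol) {
  w <- init$w; mu <- init$mu; sigma <- pmax(init$sigma, 1e-6)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    g2 <- d2 / tot
    g1 <- 1 - g2
    n1 <- sum(g1); n2 <- sum(g2)
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    sigma <- pmax(sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                         sum(g2 * (x - mu[2])^2) / n2)), 1e-6)
    w <- c(n1, n2) / length(x)
    ll <- sum(log(tot))
    if (!is.finite(ll)) return(NULL)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma = sigma, loglik = ll_old)
}

#' Posterior probability of tau positivity at a given SUVR
#'
#' Posterior probability that an observation belongs to the high (tau-
#' positive) mixture component, by Bayes' rule. Returns 0 for regions flagged
#' unimodal. Vectorized over \code{suvr}.
#'
#' @param mixture a \code{\link{fit_gmm_region}} result.
#' @param suvr positive numeric vector.
#' @return probabilities in [0, 1].
#' @export
positivity_probability <- function(mixture, suvr) {
  if (any(!is.finite(suvr)) || any(suvr <= 0))
    stop("positivity_probability: suvr must be positive and finite")
  if (isTRUE(mixture$unimodal)) return(rep(0, length(suvr)))
  # work on log densities for numerical stability far in the tails
  l1 <- log(mixture$weight_low) +
    stats::dnorm(suvr, mixture$mean_low, mixture$sd_low, log = TRUE)
  l2 <- log(mixture$weight_high) +
    stats::dnorm(suvr, mixture$mean_high, mixture$sd_high, log = TRUE)
  1 / (1 + exp(l1 - l2))
}

posterior50_cutoff <- function(mixture) {
  f <- function(x) positivity_probability(mixture, x) - 0.5
  lo <- mixture$mean_low
  hi <- mixture$mean_high
  if (f(lo) < 0 && f(hi) > 0)
    return(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
  # fall back to a dense grid between the means for unusual geometries
  grid <- seq(lo, hi, length.out = 4096)
  vals <- f(grid)
  sgn <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(sgn)) return(Inf)
  stats::uniroot(f, grid[c(sgn[1], sgn[1] + 1)], tol = 1e-10)$root
}

#' SUVR positivity cutoff for a fitted mixture
#'
#' Two conventions: \code{posterior50}, the SUVR between the component means
#' at which the posterior probability of the high component equals 0.5; or
#' \code{low_mean_plus_2sd}, the tau-negative component mean plus two of its
#' SDs. Unimodal mixtures yield \code{Inf} with a warning.
#'
#' @param mixture a \code{region_mixture}.
#' @param method cutoff convention.
#' @return SUVR cutoff (possibly \code{Inf}).
#' @export
region_cutoff <- function(mixture,
                          method = c("posterior50", "low_mean_plus_2sd")) {
  method <- match.arg(method)
  if (isTRUE(mixture$unimodal)) {
    warning("region_cutoff: unimodal mixture, cutoff is Inf")
    return(Inf)
  }
  switch(method,
         posterior50 = posterior50_cutoff(mixture),
         low_mean_plus_2sd = mixture$mean_low + 2 * mixture$sd_low)
}

#' Fit mixtures for every region (or region set) of a cohort
#'
#' Fits \code{\link{fit_gmm_region}} to baseline values across participants,
#' either per region (\code{level = "region"}) or on volume-weighted ROI
#' means per supplied region set (\code{level = "set"}). By default all
#' subjects are pooled, including amyloid-negative controls, which anchors
#' the tau-negative component.
#'
#' @param cohort a \code{\link{tau_cohort}}.
#' @param level "region" or "set".
#' @param sets named list of region sets (required for \code{level = "set"}).
#' @param subjects optional logical selector restricting the fitting sample.
#' @param seed seed forwarded to each fit.
#' @param ... further arguments to \code{\link{fit_gmm_region}}.
#' @return named list of \code{region_mixture} objects.
#' @export
fit_gmm_cohort <- function(cohort, level = c("region", "set"), sets = NULL,
                           subjects = NULL, seed = 1L, ...) {
  level <- match.arg(level)
  if (is.null(subjects)) subjects <- rep(TRUE, nrow(cohort$subjects))
  bl <- cohort$baseline[subjects, , drop = FALSE]
  if (level == "region") {
    cols <- colnames(bl)
    out <- lapply(cols, function(r)
      fit_gmm_region(bl[, r], region_id = r, seed = seed, ...))
    names(out) <- cols
  } else {
    if (is.null(sets)) stop("fit_gmm_cohort: sets required at level='set'")
    out <- lapply(sets, function(s) {
      vals <- apply(bl, 1, function(row)
        weighted_roi_mean(row, s$region_ids, cohort$catalog))
      fit_gmm_region(vals, region_id = s$name, seed = seed, ...)
    })
    names(out) <- vapply(sets, `[[`, character(1), "name")
  }
  out
}

#' Serialize fitted mixtures to JSON
#' @param mixtures named list of \code{region_mixture} objects.
#' @param path output path.
#' @export
write_mixtures <- function(mixtures, path) {
  obj <- lapply(mixtures, function(m)
    list(region_id = m$region_id, weight_low = m$weight_low,
         weight_high = m$weight_high, mean_low = m$mean_low,
         mean_high = m$mean_high, sd_low = m$sd_low, sd_high = m$sd_high,
         cutoff = if (is.finite(m$cutoff)) m$cutoff else "Inf",
         unimodal = m$unimodal, n = m$n))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read fitted mixtures from JSON
#' @param path JSON written by \code{\link{write_mixtures}}.
#' @return named list of \code{region_mixture} objects.
#' @export
read_mixtures <- function(path) {
  obj <- jsonlite::read_json(path)
  out <- lapply(obj, function(m)
    new_region_mixture(m$region_id, m$weight_low, m$weight_high,
                       m$mean_low, m$mean_high, m$sd_low, m$sd_high,
                       cutoff = if (identical(m$cutoff, "Inf")) Inf
                                else as.numeric(m$cutoff),
                       unimodal = isTRUE(m$unimodal), loglik = NA_real_,
                       n = m$n))
  names(out) <- names(obj)
  out
}

#' Stage-wise tau positivity of one subject
#'
#' For each staged region set, the subject is positive when the
#' volume-weighted mean baseline SUVR over the set exceeds the set's cutoff.
#'
#' @param suvr named numeric vector (one subject's baseline SUVR).
#' @param staged_sets list of staged \code{\link{region_set}} objects
#'   (stage indices 1..K).
#' @param cutoffs named numeric vector of SUVR cutoffs, one per set name.
#' @param catalog a \code{\link{region_catalog}}.
#' @return logical vector of length K, named by set, ordered by stage index.
#' @export
stage_positivity <- function(suvr, staged_sets, cutoffs, catalog) {
  staged_sets <- staged_sets_of(staged_sets)
  nms <- vapply(staged_sets, `[[`, character(1), "name")
  if (!all(nms %in% names(cutoffs)))
    stop("stage_positivity: missing cutoff for ",
         paste(setdiff(nms, names(cutoffs)), collapse = ", "))
  out <- vapply(staged_sets, function(s)
    weighted_roi_mean(suvr, s$region_ids, catalog) > cutoffs[[s$name]],
    logical(1))
  stats::setNames(out, nms)
}
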