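#' Annualized percentage change in SUVR
#'
#' 100 * (followup - baseline) / baseline / interval_years: the change
#' between scans expressed as percent of the baseline value per year.
#'
#' @param baseline_suvr,followup_suvr positive scalars (or vectors) of ROI
#'   mean SUVR.
#' @param interval_years positive time between scans in years.
#' @return percent change per year.
#' @examples
#' annual_pct_change(1.50, 1.65, 2.0)  # 5 %/y
#' @export
annual_pct_change <- function(baseline_suvr, followup_suvr, interval_years) {
  if (any(baseline_suvr <= 0))
    stop("annual_pct_change: baseline SUVR must be positive")
  if (any(interval_years <= 0))
    stop("annual_pct_change: interval must be positive")
  100 * (followup_suvr - baseline_suvr) / baseline_suvr / interval_years
}

#' Annualized absolute change in SUVR
#'
#' (followup - baseline) / interval_years, in SUVR units per year.
#'
#' @inheritParams annual_pct_change
#' @export
annual_change <- function(baseline_suvr, followup_suvr, interval_years) {
  if (any(interval_years <= 0))
    stop("annual_change: interval must be positive")
  (followup_suvr - baseline_suvr) / interval_years
}

#' Tau extent of a voxel block
#'
#' Fraction of voxels whose SUVR exceeds a threshold — the percentage of
#' abnormal voxels within the region(s) covered by the block.
#'
#' @param vb a \code{\link{voxel_block}} already restricted to the ROI of
#'   interest (see \code{\link{subset_voxel_block}}).
#' @param threshold SUVR threshold.
#' @return fraction in [0, 1].
#' @export
tau_extent <- function(vb, threshold = 1.40) {
  n <- length(vb$voxel_suvr)
  if (n == 0L) stop("tau_extent: empty voxel block")
  sum(vb$voxel_suvr > threshold) / n
}

#' One-sample summary of per-subject change values
#'
#' Mean, t-based 95% CI and a two-sided one-sample t test against 0
#' (via \code{stats::t.test}). Zero-variance input is flagged as degenerate
#' with p reported below 1e-15.
#'
#' @param values numeric vector of per-subject changes (n >= 2).
#' @param roi,group optional labels carried into the result.
#' @param conf_level confidence level of the CI.
#' @return data.frame with columns group, roi, n, mean, ci95_low, ci95_high,
#'   t_statistic, p_value, degenerate.
#' @export
one_sample_summary <- function(values, roi = NA_character_,
                               group = NA_character_, conf_level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("one_sample_summary: need at least 2 finite values")
  if (stats::sd(values) == 0) {
    m <- mean(values)
    return(data.frame(group = group, roi = roi, n = n, mean = m,
                      ci95_low = m, ci95_high = m,
                      t_statistic = if (m == 0) 0 else Inf * sign(m),
                      p_value = if (m == 0) 1 else 1e-16,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(values, mu = 0, conf.level = conf_level)
  data.frame(group = group, roi = roi, n = n, mean = unname(tt$estimate),
             ci95_low = tt$conf.int[1], ci95_high = tt$conf.int[2],
             t_statistic = unname(tt$statistic),
             p_value = tt$p.value, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Per-subject change records for a set of ROIs
#'
#' Aggregates each scan to the ROI mean first, then computes annualized
#' change — one row per subject x ROI. ROIs may be shared region sets or
#' per-subject \code{\link{individual_roi}} objects; voxel-mask ROIs
#' (overlap method) average the voxel SUVR over the mask at each timepoint.
#'
#' @param cohort a \code{\link{tau_cohort}}.
#' @param rois either a named list of \code{\link{region_set}} objects
#'   (applied to every subject) or a named-by-subject list of
#'   \code{\link{individual_roi}} objects.
#' @param roi_name label used when \code{rois} is per-subject.
#' @param voxel_blocks per-subject list with \code{$baseline} /
#'   \code{$followup} \code{voxel_block}s; required for voxel-mask ROIs.
#' @param weighted volume-weighted region means.
#' @return data.frame with columns subject_id, roi_name, baseline_suvr,
#'   followup_suvr, interval_years, annual_pct_change, annual_change.
#' @export
change_table <- function(cohort, rois, roi_name = NULL, voxel_blocks = NULL,
                         weighted = TRUE) {
  s <- cohort$subjects
  if (length(rois) && inherits(rois[[1]], "individual_roi")) {
    rows <- lapply(names(rois), function(sid) {
      roi <- rois[[sid]]
      dt <- s$interval_years[s$subject_id == sid]
      if (!is.null(roi$voxel_mask)) {
        vb <- voxel_blocks[[sid]]
        if (is.null(vb))
          stop("change_table: voxel blocks required for subject ", sid)
        bl <- mean(subset_voxel_block(vb$baseline,
                                      mask = roi$voxel_mask)$voxel_suvr)
        fu <- mean(subset_voxel_block(vb$followup,
                                      mask = roi$voxel_mask)$voxel_suvr)
      } else {
        bl <- weighted_roi_mean(cohort$baseline[sid, ], roi$region_ids,
                                cohort$catalog, weighted)
        fu <- weighted_roi_mean(cohort$followup[sid, ], roi$region_ids,
                                cohort$catalog, weighted)
      }
      data.frame(subject_id = sid,
                 roi_name = if (is.null(roi_name)) roi$method else roi_name,
                 baseline_suvr = bl, followup_suvr = fu,
                 interval_years = dt,
                 annual_pct_change = annual_pct_change(bl, fu, dt),
                 annual_change = annual_change(bl, fu, dt),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    rows <- lapply(rois, function(set) {
      bl <- apply(cohort$baseline, 1, weighted_roi_mean, set$region_ids,
                  cohort$catalog, weighted)
      fu <- apply(cohort$followup, 1, weighted_roi_mean, set$region_ids,
                  cohort$catalog, weighted)
      data.frame(subject_id = s$subject_id, roi_name = set$name,
                 baseline_suvr = unname(bl), followup_suvr = unname(fu),
                 interval_years = s$interval_years,
                 annual_pct_change = annual_pct_change(bl, fu,
                                                       s$interval_years),
                 annual_change = annual_change(bl, fu, s$interval_years),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}
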