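#' Construct a participant-specific ROI
#'
#' Exactly one of \code{region_ids} (region-based methods) or
#' \code{voxel_mask} (the overlap-index method) must be populated.
#' \code{provenance} records how the ROI was derived (epicenter, selected
#' probability interval, overlap threshold and mask sizes, selected stage, or
#' subtype/stage/band).
#'
#' @param subject_id subject identifier.
#' @param method one of "q1", "probability", "overlap", "highest_dds",
#'   "sustain".
#' @param region_ids character vector of member regions (region methods).
#' @param voxel_mask logical vector (overlap method).
#' @param provenance named list of method-specific details.
#' @return list of class \code{individual_roi}.
#' @export
individual_roi <- function(subject_id, method, region_ids = character(0),
                           voxel_mask = NULL, provenance = list()) {
  method <- match.arg(method,
                      c("q1", "probability", "overlap", "highest_dds",
                        "sustain"))
  has_regions <- length(region_ids) > 0L
  has_mask <- !is.null(voxel_mask)
  if (has_regions == has_mask)
    stop("individual_roi: exactly one of region_ids / voxel_mask must be set")
  structure(list(subject_id = subject_id, method = method,
                 region_ids = as.character(region_ids),
                 voxel_mask = voxel_mask, provenance = provenance),
            class = "individual_roi")
}

#' Participant-specific tau epicenter
#'
#' The epicenter is the top fraction (default 10%) of catalog regions with
#' the highest probability of abnormal tau-PET signal, i.e. the
#' ceiling(fraction * N) highest-probability regions. Ties are broken
#' lexicographically by region id so the selection is deterministic.
#'
#' @param prob_by_region named numeric vector of tau-positivity
#'   probabilities in [0, 1], one per catalog region.
#' @param fraction fraction of regions to select, in (0, 1).
#' @return character vector of epicenter region ids.
#' @export
define_epicenter <- function(prob_by_region, fraction = 0.10) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("define_epicenter: fraction must lie in (0, 1)")
  if (any(!is.finite(prob_by_region)) ||
      any(prob_by_region < 0 | prob_by_region > 1))
    stop("define_epicenter: probabilities must lie in [0, 1]")
  n_pick <- ceiling(fraction * length(prob_by_region))
  ord <- order(-prob_by_region, names(prob_by_region))
  names(prob_by_region)[ord[seq_len(n_pick)]]
}

#' Connectivity quartiles relative to an epicenter
#'
#' Scores every non-epicenter region by its mean shortest-path distance to
#' the epicenter regions and splits the ascending ordering into four
#' nonoverlapping quartiles whose sizes differ by at most one (remainder
#' regions go to the earlier quartiles). Quartile 1 — the regions with the
#' strongest connectivity to the epicenter — is the participant's ROI; the
#' epicenter itself is excluded unless \code{include_epicenter} is set.
#' Ties in distance are broken lexicographically by region id.
#'
#' @param distances distance matrix from
#'   \code{\link{connectivity_to_distance}}.
#' @param epicenter character vector of epicenter region ids.
#' @param subject_id identifier recorded in the result.
#' @param include_epicenter also include the epicenter regions in the
#'   returned ROI (sensitivity option, default FALSE).
#' @return an \code{\link{individual_roi}} (method "q1") whose provenance
#'   holds the epicenter, the full quartile assignment and the scores.
#' @export
quartile_q1_roi <- function(distances, epicenter, subject_id = NA_character_,
                            include_epicenter = FALSE) {
  if (length(epicenter) == 0L) stop("quartile_q1_roi: empty epicenter")
  regions <- rownames(distances)
  if (!all(epicenter %in% regions))
    stop("quartile_q1_roi: epicenter regions absent from distance matrix")
  rest <- setdiff(regions, epicenter)
  score <- rowMeans(distances[rest, epicenter, drop = FALSE])
  if (all(is.infinite(score)))
    stop("quartile_q1_roi: all non-epicenter regions unreachable")
  ord <- rest[order(score, rest)]
  n <- length(ord)
  base <- n %/% 4L
  sizes <- base + (seq_len(4L) <= n %% 4L)
  quartile <- rep(seq_len(4L), times = sizes)
  q1 <- ord[quartile == 1L]
  roi_ids <- if (include_epicenter) c(epicenter, q1) else q1
  individual_roi(subject_id, "q1", region_ids = roi_ids,
                 provenance = list(epicenter = epicenter,
                                   quartile = stats::setNames(quartile, ord),
                                   distance = stats::setNames(
                                     unname(score[ord]), ord)))
}

#' Probability-interval ROI search
#'
#' For each candidate probability interval [lo, hi] (all combinations of the
#' lower and upper start values), each subject's ROI is the set of regions
#' whose tau-positivity probability lies inside the closed interval. The
#' interval whose ROIs yield the highest mean annual percentage change in
#' SUVR across the evaluated subjects wins; ties prefer the narrower
#' interval, then the lower start. Subjects with an empty ROI under an
#' interval are excluded from that interval's mean (and logged for the
#' winner).
#'
#' @param prob matrix of tau-positivity probabilities, subjects x regions
#'   (dimnames required), from the baseline scans.
#' @param cohort a \code{\link{tau_cohort}}.
#' @param subjects logical selector of the evaluated group (default all).
#' @param lower_starts,uppers candidate interval endpoints.
#' @param weighted volume-weighted ROI means.
#' @return list with \code{interval} (winning c(lo, hi)), \code{rois} (named
#'   list of \code{individual_roi} under the winner), \code{search} (one row
#'   per candidate: lo, hi, n_used, mean_change), and \code{excluded}
#'   (subject ids with empty winning ROI).
#' @export
probability_interval_search <- function(prob, cohort, subjects = NULL,
                                        lower_starts = c(0.2, 0.3, 0.4),
                                        uppers = c(0.7, 0.8, 0.9, 1.0),
                                        weighted = TRUE) {
  if (is.null(subjects)) subjects <- rep(TRUE, nrow(cohort$subjects))
  ids <- cohort$subjects$subject_id[subjects]
  grid <- expand.grid(lo = lower_starts, hi = uppers,
                      KEEP.OUT.ATTRS = FALSE)
  eval_interval <- function(lo, hi) {
    changes <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
      sid <- ids[i]
      p <- prob[sid, ]
      sel <- names(p)[p >= lo & p <= hi]
      if (!length(sel)) next
      bl <- weighted_roi_mean(cohort$baseline[sid, ], sel, cohort$catalog,
                              weighted)
      fu <- weighted_roi_mean(cohort$followup[sid, ], sel, cohort$catalog,
                              weighted)
      dt <- cohort$subjects$interval_years[cohort$subjects$subject_id == sid]
      changes[i] <- annual_pct_change(bl, fu, dt)
    }
    changes
  }
  grid$n_used <- NA_integer_
  grid$mean_change <- NA_real_
  for (k in seq_len(nrow(grid))) {
    ch <- eval_interval(grid$lo[k], grid$hi[k])
    grid$n_used[k] <- sum(!is.na(ch))
    grid$mean_change[k] <- if (any(!is.na(ch))) mean(ch, na.rm = TRUE)
                           else -Inf
  }
  # winner: highest mean change; ties -> narrower interval, then lower lo
  ord <- order(-grid$mean_change, grid$hi - grid$lo, grid$lo)
  win <- grid[ord[1], ]
  rois <- list()
  excluded <- character(0)
  for (sid in ids) {
    p <- prob[sid, ]
    sel <- names(p)[p >= win$lo & p <= win$hi]
    if (!length(sel)) { excluded <- c(excluded, sid); next }
    rois[[sid]] <- individual_roi(sid, "probability", region_ids = sel,
                                  provenance = list(interval =
                                                      c(win$lo, win$hi)))
  }
  list(interval = c(lo = win$lo, hi = win$hi), rois = rois,
       search = grid, excluded = excluded)
}

#' Overlap-index ROI from two voxel blocks
#'
#' Binarizes the baseline and follow-up voxel SUVR maps at a threshold
#' (default 1.40), restricts to the gray-matter mask, and takes the
#' intersection: voxels abnormal at both timepoints. The overlap index
#' |intersection| / |union| is recorded in the provenance. An empty
#' intersection yields \code{NULL} (the subject is excluded for this
#' method).
#'
#' @param baseline,followup \code{voxel_block} objects of the same subject
#'   with aligned voxel arrays and identical gray-matter masks.
#' @param threshold SUVR threshold defining abnormal voxels.
#' @return an \code{\link{individual_roi}} (method "overlap") carrying the
#'   voxel mask, or \code{NULL} when the masks do not intersect.
#' @export
overlap_index_roi <- function(baseline, followup, threshold = 1.40) {
  if (length(baseline$voxel_suvr) != length(followup$voxel_suvr))
    stop("overlap_index_roi: voxel arrays not aligned")
  if (!identical(baseline$gm_mask, followup$gm_mask))
    stop("overlap_index_roi: gray-matter masks differ between timepoints")
  gm <- baseline$gm_mask
  m_bl <- (baseline$voxel_suvr > threshold) & gm
  m_fu <- (followup$voxel_suvr > threshold) & gm
  inter <- m_bl & m_fu
  uni <- m_bl | m_fu
  if (!any(inter)) return(NULL)
  individual_roi(baseline$subject_id, "overlap", voxel_mask = inter,
                 provenance = list(threshold = threshold,
                                   n_baseline = sum(m_bl),
                                   n_followup = sum(m_fu),
                                   n_intersection = sum(inter),
                                   overlap_index = sum(inter) / sum(uni)))
}

#' Highest tau-positive stage ROI
#'
#' Given a subject's stage-wise positivity vector, the ROI is the staged set
#' with the largest positive stage index — the region set affected most
#' recently in the tau accumulation cascade (e.g. positivity in stages
#' 1–4 selects the stage-4 set). Noncontiguous positivity patterns
#' (hierarchy violations) still use the maximum positive index and are
#' flagged in the provenance. Subjects with no positive stage fall back to
#' the stage-1 set with a flag by default, or are excluded.
#'
#' @param pos_vector logical vector, one entry per staged set in stage
#'   order.
#' @param staged_sets list of staged \code{\link{region_set}} objects.
#' @param subject_id identifier recorded in the result.
#' @param fallback "stage1" (default) or "exclude" for all-negative
#'   subjects.
#' @return an \code{\link{individual_roi}} (method "highest_dds"), or
#'   \code{NULL} under \code{fallback = "exclude"}.
#' @export
highest_positive_dds_roi <- function(pos_vector, staged_sets,
                                     subject_id = NA_character_,
                                     fallback = c("stage1", "exclude")) {
  fallback <- match.arg(fallback)
  staged_sets <- staged_sets_of(staged_sets)
  if (length(pos_vector) != length(staged_sets))
    stop("pos_vector length must equal the number of staged sets")
  pos_idx <- which(pos_vector)
  violation <- length(pos_idx) > 0L &&
    !identical(pos_idx, seq_len(max(pos_idx)))
  if (length(pos_idx) == 0L) {
    if (fallback == "exclude") return(NULL)
    sel <- 1L
    flagged <- TRUE
  } else {
    sel <- max(pos_idx)
    flagged <- FALSE
  }
  set <- staged_sets[[sel]]
  individual_roi(subject_id, "highest_dds", region_ids = set$region_ids,
                 provenance = list(stage_index = set$stage_index,
                                   set_name = set$name,
                                   all_negative_fallback = flagged,
                                   hierarchy_violation = violation))
}
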