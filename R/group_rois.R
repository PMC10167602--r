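weighted_roi_mean <- function(suvr, region_ids, catalog, weighted = TRUE) {
  if (length(region_ids) == 0L) stop("empty region set")
  missing <- setdiff(region_ids, names(suvr))
  if (length(missing))
    stop("subject is missing region(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  v <- suvr[region_ids]
  if (!weighted) return(mean(v))
  w <- catalog_volumes(catalog, region_ids)
  sum(v * w) / sum(w)
}

#' ROI mean SUVR for one scan
#'
#' Volume-weighted (default) or unweighted mean of regional SUVR over a
#' region set; the same computation applied identically to every participant
#' yields the group-level ROI readout.
#'
#' @param suvr named numeric vector of a subject-timepoint's regional SUVR.
#' @param set a \code{\link{region_set}} (or character vector of region ids).
#' @param catalog a \code{\link{region_catalog}}.
#' @param weighted use volume weights (default TRUE).
#' @return scalar mean SUVR.
#' @export
group_roi_suvr <- function(suvr, set, catalog, weighted = TRUE) {
  ids <- if (inherits(set, "region_set")) set$region_ids else
    as.character(set)
  weighted_roi_mean(suvr, ids, catalog, weighted = weighted)
}

#' ROI SUVR table for a cohort
#'
#' Long-format table of ROI mean SUVR: one row per subject x ROI x timepoint.
#'
#' @param cohort a \code{\link{tau_cohort}}.
#' @param sets named list of \code{\link{region_set}} objects.
#' @param weighted use volume weights.
#' @return data.frame with columns subject_id, roi_name, timepoint,
#'   suvr_mean.
#' @export
roi_suvr_table <- function(cohort, sets, weighted = TRUE) {
  ids <- cohort$subjects$subject_id
  rows <- lapply(sets, function(s) {
    bl <- apply(cohort$baseline, 1, weighted_roi_mean, s$region_ids,
                cohort$catalog, weighted)
    fu <- apply(cohort$followup, 1, weighted_roi_mean, s$region_ids,
                cohort$catalog, weighted)
    rbind(data.frame(subject_id = ids, roi_name = s$name,
                     timepoint = "baseline", suvr_mean = unname(bl),
                     stringsAsFactors = FALSE),
          data.frame(subject_id = ids, roi_name = s$name,
                     timepoint = "followup", suvr_mean = unname(fu),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
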