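#' Construct a two-timepoint longitudinal tau-PET cohort
#'
#' Stores per-subject, per-region SUVR at baseline and follow-up as two
#' aligned subject-by-region matrices, together with subject metadata
#' (diagnostic group, amyloid status, scan interval) and the region catalog.
#'
#' @param subjects data.frame with columns \code{subject_id}, \code{group}
#'   (one of CU/MCI/AD), \code{abeta} ("positive"/"negative"),
#'   \code{interval_years} (> 0).
#' @param baseline,followup numeric matrices, one row per subject (rownames =
#'   subject_id), one column per region (colnames = region_id); all values > 0.
#' @param catalog a \code{\link{region_catalog}} covering all columns.
#' @param dropped optional data.frame recording subjects dropped on ingest.
#' @return object of class \code{tau_cohort}.
#' @export
tau_cohort <- function(subjects, baseline, followup, catalog,
                       dropped = NULL) {
  subjects$subject_id <- as.character(subjects$subject_id)
  needed <- c("subject_id", "group", "abeta", "interval_years")
  if (!all(needed %in% names(subjects)))
    stop("subjects must have columns ", paste(needed, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in cohort")
  if (!all(subjects$group %in% c("CU", "MCI", "AD")))
    stop("group must be one of CU, MCI, AD")
  if (!all(subjects$abeta %in% c("positive", "negative")))
    stop("abeta must be 'positive' or 'negative'")
  if (any(!is.finite(subjects$interval_years) | subjects$interval_years <= 0))
    stop("interval_years must be finite and > 0 for every subject")
  for (nm in c("baseline", "followup")) {
    m <- get(nm)
    if (!identical(rownames(m), subjects$subject_id))
      stop(nm, " rownames must equal subjects$subject_id (same order)")
    if (any(!is.finite(m)) || any(m <= 0)) {
      bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)[1, ]
      stop("nonpositive or non-finite SUVR in ", nm, " for subject '",
           rownames(m)[bad[1]], "', region '", colnames(m)[bad[2]], "'")
    }
  }
  if (!identical(colnames(baseline), colnames(followup)))
    stop("baseline and followup must share identical region_id sets")
  missing <- setdiff(colnames(baseline), catalog$region_id)
  if (length(missing))
    stop("scan regions absent from catalog: ",
         paste(utils::head(missing, 5), collapse = ", "))
  structure(list(subjects = subjects, baseline = baseline,
                 followup = followup, catalog = catalog,
                 dropped = if (is.null(dropped))
                   data.frame(subject_id = character(0),
                              reason = character(0)) else dropped),
            class = "tau_cohort")
}

#' @export
print.tau_cohort <- function(x, ...) {
  tab <- table(x$subjects$group, x$subjects$abeta)
  cat("tau_cohort:", nrow(x$subjects), "subjects,",
      ncol(x$baseline), "regions\n")
  print(tab)
  cat("mean scan interval:",
      round(mean(x$subjects$interval_years), 2), "years\n")
  if (nrow(x$dropped)) cat("dropped on ingest:", nrow(x$dropped), "\n")
  invisible(x)
}

#' Subjects in the amyloid-negative control group
#'
#' Controls (used for mixture fitting support and z-scoring) are the
#' amyloid-negative cognitively unimpaired subjects.
#'
#' @param cohort a \code{\link{tau_cohort}}.
#' @return logical vector over cohort subjects.
#' @export
is_control <- function(cohort) {
  cohort$subjects$abeta == "negative" & cohort$subjects$group == "CU"
}

#' Analysis groups of a cohort
#'
#' The three analysis strata: amyloid-positive CU, amyloid-positive MCI, and
#' AD dementia. Returns a named list of logical subject selectors.
#' @param cohort a \code{\link{tau_cohort}}.
#' @export
analysis_groups <- function(cohort) {
  s <- cohort$subjects
  list(CU  = s$group == "CU"  & s$abeta == "positive",
       MCI = s$group == "MCI" & s$abeta == "positive",
       AD  = s$group == "AD")
}

wide_meta_cols <- c("subject_id", "timepoint", "years_from_baseline",
                    "group", "abeta")

#' Read a longitudinal cohort from a delimited table
#'
#' Two dialects are supported. \emph{Wide}: one row per subject-timepoint with
#' columns \code{subject_id}, \code{timepoint} (baseline/followup),
#' \code{years_from_baseline}, \code{group}, \code{abeta}, then one numeric
#' column per region. \emph{Long}: columns \code{subject_id},
#' \code{timepoint}, \code{region_id}, \code{suvr}, plus the same metadata
#' columns (repeated per row). Subjects missing either timepoint are dropped
#' and recorded in the cohort's \code{dropped} table.
#'
#' @param path delimited text file.
#' @param dialect "wide" (default) or "long".
#' @param catalog optional \code{\link{region_catalog}}; if omitted, a catalog
#'   with unit volumes is synthesized from the observed regions.
#' @param sep field delimiter (tab by default).
#' @return a \code{\link{tau_cohort}}.
#' @export
read_cohort <- function(path, dialect = c("wide", "long"), catalog = NULL,
                        sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (dialect == "wide") {
    missing <- setdiff(wide_meta_cols, names(tab))
    if (length(missing))
      stop("malformed header: missing column(s) ",
           paste(missing, collapse = ", "))
    region_ids <- setdiff(names(tab), wide_meta_cols)
  } else {
    needed <- c("subject_id", "timepoint", "region_id", "suvr",
                "years_from_baseline", "group", "abeta")
    missing <- setdiff(needed, names(tab))
    if (length(missing))
      stop("malformed header: missing column(s) ",
           paste(missing, collapse = ", "))
    region_ids <- sort(unique(as.character(tab$region_id)))
    # pivot to wide
    key <- paste(tab$subject_id, tab$timepoint, sep = "\r")
    meta <- tab[!duplicated(key),
                c("subject_id", "timepoint", "years_from_baseline",
                  "group", "abeta")]
    m <- matrix(NA_real_, nrow(meta), length(region_ids),
                dimnames = list(NULL, region_ids))
    row_of <- match(key, paste(meta$subject_id, meta$timepoint, sep = "\r"))
    col_of <- match(as.character(tab$region_id), region_ids)
    m[cbind(row_of, col_of)] <- tab$suvr
    tab <- cbind(meta, as.data.frame(m, check.names = FALSE))
  }
  if (!all(tab$timepoint %in% c("baseline", "followup")))
    stop("timepoint must be 'baseline' or 'followup'")
  bl <- tab[tab$timepoint == "baseline", , drop = FALSE]
  fu <- tab[tab$timepoint == "followup", , drop = FALSE]
  ids <- union(bl$subject_id, fu$subject_id)
  keep <- intersect(bl$subject_id, fu$subject_id)
  dropped_ids <- setdiff(ids, keep)
  dropped <- data.frame(subject_id = dropped_ids,
                        reason = rep("missing baseline or followup scan",
                                     length(dropped_ids)),
                        stringsAsFactors = FALSE)
  if (length(dropped_ids))
    message("read_cohort: dropped ", length(dropped_ids),
            " subject(s) missing a timepoint")
  bl <- bl[match(keep, bl$subject_id), , drop = FALSE]
  fu <- fu[match(keep, fu$subject_id), , drop = FALSE]
  if (any(bl$years_from_baseline != 0))
    stop("baseline rows must have years_from_baseline = 0")
  blm <- as.matrix(bl[, region_ids, drop = FALSE])
  fum <- as.matrix(fu[, region_ids, drop = FALSE])
  storage.mode(blm) <- storage.mode(fum) <- "double"
  rownames(blm) <- rownames(fum) <- keep
  subjects <- data.frame(subject_id = keep, group = bl$group,
                         abeta = bl$abeta,
                         interval_years = fu$years_from_baseline,
                         stringsAsFactors = FALSE)
  if (is.null(catalog))
    catalog <- region_catalog(region_ids, volume = rep(1, length(region_ids)))
  tau_cohort(subjects, blm, fum, catalog, dropped = dropped)
}

#' Write a cohort to a delimited table
#'
#' Inverse of \code{\link{read_cohort}}; round-trips losslessly.
#'
#' @param cohort a \code{\link{tau_cohort}}.
#' @param path output path.
#' @param dialect "wide" or "long".
#' @param sep field delimiter.
#' @export
write_cohort <- function(cohort, path, dialect = c("wide", "long"),
                         sep = "\t") {
  dialect <- match.arg(dialect)
  s <- cohort$subjects
  make_rows <- function(m, tp, years) {
    cbind(data.frame(subject_id = s$subject_id, timepoint = tp,
                     years_from_baseline = years, group = s$group,
                     abeta = s$abeta, stringsAsFactors = FALSE),
          as.data.frame(m, check.names = FALSE))
  }
  wide <- rbind(make_rows(cohort$baseline, "baseline", 0),
                make_rows(cohort$followup, "followup", s$interval_years))
  if (dialect == "long") {
    region_ids <- colnames(cohort$baseline)
    long <- do.call(rbind, lapply(region_ids, function(r) {
      data.frame(subject_id = wide$subject_id, timepoint = wide$timepoint,
                 region_id = r, suvr = wide[[r]],
                 years_from_baseline = wide$years_from_baseline,
                 group = wide$group, abeta = wide$abeta,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(long, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    utils::write.table(wide, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Normalize regional uptake to a reference region
#'
#' Converts raw regional tracer uptake to SUVR by dividing by the
#' volume-weighted mean uptake over a set of reference regions (e.g. the
#' inferior cerebellar cortex). Scale-invariant: multiplying all uptakes by a
#' positive constant leaves the SUVR unchanged.
#'
#' @param uptake named numeric vector of regional uptake values.
#' @param reference_ids region ids forming the reference region.
#' @param catalog a \code{\link{region_catalog}} (for reference volumes).
#' @return named numeric vector of SUVR values (reference mean = 1 by
#'   construction over the reference set).
#' @export
normalize_to_reference <- function(uptake, reference_ids, catalog) {
  reference_ids <- as.character(reference_ids)
  if (length(reference_ids) == 0L)
    stop("normalize_to_reference: empty reference set")
  if (!all(reference_ids %in% names(uptake)))
    stop("reference regions absent from uptake vector")
  vols <- catalog_volumes(catalog, reference_ids)
  ref <- sum(uptake[reference_ids] * vols) / sum(vols)
  if (!is.finite(ref) || ref <= 0)
    stop("reference uptake must be positive")
  uptake / ref
}
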