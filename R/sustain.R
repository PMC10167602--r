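#' Construct an event-sequence subtype/stage model
#'
#' A fixed, pre-trained subtype-and-stage model: for each subtype, an ordered
#' sequence of (region, z-threshold) events. A subject at stage k of subtype
#' s is expected to have reached the threshold of every event at position
#' <= k and none after. Thresholds for repeated events of one region must be
#' increasing along the sequence.
#'
#' @param event_sequences list (one element per subtype) of data.frames with
#'   columns \code{region_id} and \code{z_threshold}; all sequences must have
#'   equal length (the number of stages).
#' @param subtype_priors prior probabilities per subtype (default uniform).
#' @param z_max per-region ceiling of the final event (informational).
#' @return list of class \code{sustain_model} with fields
#'   \code{n_subtypes}, \code{n_stages}, \code{event_sequences},
#'   \code{subtype_priors}, \code{z_max}, \code{regions}.
#' @export
sustain_model <- function(event_sequences, subtype_priors = NULL,
                          z_max = NULL) {
  n_subtypes <- length(event_sequences)
  lens <- vapply(event_sequences, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("sustain_model: all event sequences must have equal length")
  n_stages <- lens[1]
  for (s in seq_len(n_subtypes)) {
    seq_s <- event_sequences[[s]]
    if (!all(c("region_id", "z_threshold") %in% names(seq_s)))
      stop("sustain_model: sequences need region_id and z_threshold columns")
    for (r in unique(seq_s$region_id)) {
      th <- seq_s$z_threshold[seq_s$region_id == r]
      if (is.unsorted(th, strictly = TRUE) && length(th) > 1L)
        stop("sustain_model: thresholds of region '", r,
             "' in subtype ", s, " must increase along the sequence")
    }
  }
  if (is.null(subtype_priors))
    subtype_priors <- rep(1 / n_subtypes, n_subtypes)
  if (abs(sum(subtype_priors) - 1) > 1e-9)
    stop("sustain_model: subtype priors must sum to 1")
  regions <- sort(unique(unlist(lapply(event_sequences,
                                       `[[`, "region_id"))))
  if (is.null(z_max)) {
    z_max <- vapply(regions, function(r)
      max(unlist(lapply(event_sequences, function(sq)
        c(0, sq$z_threshold[sq$region_id == r])))), numeric(1))
  }
  structure(list(n_subtypes = n_subtypes, n_stages = n_stages,
                 event_sequences = event_sequences,
                 subtype_priors = subtype_priors, z_max = z_max,
                 regions = regions),
            class = "sustain_model")
}

#' Expected z-score pattern at a given subtype and stage
#'
#' For each region appearing in any event of the model, the expected
#' z-score of a subject at (subtype, stage): the largest threshold among the
#' subtype's events for that region at positions <= stage, or 0 if none.
#'
#' @param model a \code{\link{sustain_model}}.
#' @param subtype subtype index (ignored at stage 0).
#' @param stage stage in 0..n_stages.
#' @return named numeric vector over \code{model$regions}.
#' @export
sustain_expected_z <- function(model, subtype, stage) {
  out <- stats::setNames(rep(0, length(model$regions)), model$regions)
  if (stage == 0L) return(out)
  sq <- model$event_sequences[[subtype]]
  done <- sq[seq_len(stage), , drop = FALSE]
  for (i in seq_len(nrow(done)))
    out[done$region_id[i]] <- max(out[done$region_id[i]],
                                  done$z_threshold[i])
  out
}

#' z-scores of a subject's regional SUVR versus a control sample
#'
#' @param suvr named numeric vector of regional SUVR.
#' @param control_mean,control_sd named numeric vectors of the control
#'   group's per-region mean and SD.
#' @return named numeric z-score vector over the intersection of names.
#' @export
zscore_to_controls <- function(suvr, control_mean, control_sd) {
  regions <- intersect(names(suvr), names(control_mean))
  if (any(control_sd[regions] <= 0))
    stop("zscore_to_controls: control SD must be positive")
  (suvr[regions] - control_mean[regions]) / control_sd[regions]
}

#' Maximum-likelihood subtype and stage assignment
#'
#' Scans all subtypes x stages 0..n_stages under a Gaussian event model:
#' the likelihood of the observed z-scores given (subtype, stage) is the
#' product of N(z_r; expected_r, sigma^2) over all regions in the model,
#' where the expected value is \code{\link{sustain_expected_z}}. The
#' participant ROI is the union of regions whose events fall in the stage
#' band containing the assigned stage (bands 1–10, 11–20, 21–30 for a
#' 30-stage model). Stage 0 (no event passed) yields no ROI.
#'
#' @param z named numeric vector of regional z-scores (must cover
#'   \code{model$regions}).
#' @param model a \code{\link{sustain_model}}.
#' @param subject_id identifier recorded in the ROI.
#' @param sigma event-model noise SD (default 1).
#' @param n_bands number of stage bands for the ROI (default 3).
#' @return list with \code{subtype} (NA at stage 0), \code{stage},
#'   \code{band}, \code{loglik}, and \code{roi} (an
#'   \code{\link{individual_roi}}, or \code{NULL} at stage 0).
#' @export
sustain_assign <- function(z, model, subject_id = NA_character_, sigma = 1,
                           n_bands = 3L) {
  missing <- setdiff(model$regions, names(z))
  if (length(missing))
    stop("sustain_assign: z-scores missing for ",
         paste(utils::head(missing, 5), collapse = ", "))
  z <- z[model$regions]
  best <- list(subtype = NA_integer_, stage = 0L, loglik = -Inf)
  for (s in seq_len(model$n_subtypes)) {
    for (k in 0:model$n_stages) {
      if (k == 0L && s > 1L) next  # stage 0 identical across subtypes
      e <- sustain_expected_z(model, s, k)
      ll <- sum(stats::dnorm(z, e, sigma, log = TRUE)) +
        log(model$subtype_priors[s])
      if (ll > best$loglik + 1e-12) {
        best <- list(subtype = if (k == 0L) NA_integer_ else s,
                     stage = k, loglik = ll)
      }
    }
  }
  if (best$stage == 0L)
    return(list(subtype = NA_integer_, stage = 0L, band = NA_integer_,
                loglik = best$loglik, roi = NULL))
  band_width <- ceiling(model$n_stages / n_bands)
  band <- ceiling(best$stage / band_width)
  lo <- (band - 1L) * band_width + 1L
  hi <- min(band * band_width, model$n_stages)
  sq <- model$event_sequences[[best$subtype]]
  roi_ids <- unique(sq$region_id[lo:hi])
  roi <- individual_roi(subject_id, "sustain", region_ids = roi_ids,
                        provenance = list(subtype = best$subtype,
                                          stage = best$stage, band = band,
                                          band_stages = c(lo, hi)))
  list(subtype = best$subtype, stage = best$stage, band = band,
       loglik = best$loglik, roi = roi)
}

#' Write a subtype/stage model to JSON
#' @param model a \code{\link{sustain_model}}.
#' @param path output path.
#' @export
write_sustain_model <- function(model, path) {
  obj <- list(
    n_subtypes = model$n_subtypes, n_stages = model$n_stages,
    subtype_priors = model$subtype_priors,
    z_max = as.list(model$z_max),
    event_sequences = lapply(model$event_sequences, function(sq)
      list(region_id = sq$region_id, z_threshold = sq$z_threshold)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a subtype/stage model from JSON
#' @param path JSON written by \code{\link{write_sustain_model}}.
#' @return a \code{\link{sustain_model}}.
#' @export
read_sustain_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  seqs <- lapply(obj$event_sequences, function(sq)
    data.frame(region_id = sq$region_id, z_threshold = sq$z_threshold,
               stringsAsFactors = FALSE))
  sustain_model(seqs, subtype_priors = obj$subtype_priors,
                z_max = unlist(obj$z_max))
}
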