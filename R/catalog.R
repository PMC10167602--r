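#' Build a region catalog
#'
#' A region catalog enumerates the parcellation used by a study: one row per
#' region with a unique identifier, a free-text name, an atlas tag and a
#' positive volume (mm^3 or voxel count) used for volume-weighted ROI means.
#' Region identifiers are opaque strings matched exactly; no atlas lookup is
#' performed, so any parcellation (Schaefer, FreeSurfer, ...) can be used.
#'
#' @param region_id character vector of unique region identifiers.
#' @param volume positive numeric vector of region volumes.
#' @param region_name optional character vector of display names.
#' @param atlas_tag single string naming the parcellation.
#' @return A data.frame of class \code{region_catalog} with columns
#'   \code{region_id}, \code{region_name}, \code{atlas_tag}, \code{volume}.
#' @examples
#' region_catalog(c("ctx_lh_a", "ctx_lh_b"), volume = c(1200, 800))
#' @export
region_catalog <- function(region_id, volume, region_name = region_id,
                           atlas_tag = "custom") {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id))
    stop("region_catalog: region_id values must be unique")
  if (length(volume) != length(region_id))
    stop("region_catalog: volume must have one entry per region")
  volume <- as.numeric(volume)
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("region_catalog: all volumes must be finite and > 0")
  out <- data.frame(region_id = region_id,
                    region_name = as.character(region_name),
                    atlas_tag = atlas_tag,
                    volume = volume,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_catalog", "data.frame")
  out
}

catalog_volumes <- function(catalog, region_ids) {
  idx <- match(region_ids, catalog$region_id)
  if (anyNA(idx))
    stop("regions not in catalog: ",
         paste(region_ids[is.na(idx)], collapse = ", "))
  stats::setNames(catalog$volume[idx], region_ids)
}

#' Construct a named region set
#'
#' Region sets are the building blocks of group-level ROIs: ordered
#' data-driven stages (stage_index 1..K), Braak-stage pairs, or unordered
#' composites such as the temporal and whole-brain meta-ROIs.
#'
#' @param name set name, e.g. \code{"DDS_I"} or \code{"temporal_meta"}.
#' @param region_ids nonempty character vector of member regions.
#' @param stage_index optional integer >= 1 for staged sets, \code{NA} for
#'   unordered composites.
#' @return list of class \code{region_set}.
#' @export
region_set <- function(name, region_ids, stage_index = NA_integer_) {
  region_ids <- unique(as.character(region_ids))
  if (length(region_ids) == 0L) stop("region_set: region_ids must be nonempty")
  if (!is.na(stage_index) && stage_index < 1)
    stop("region_set: stage_index must be >= 1")
  structure(list(name = name, region_ids = region_ids,
                 stage_index = as.integer(stage_index)),
            class = "region_set")
}

#' Validate a list of region sets against a catalog
#'
#' Checks membership in the catalog and, for staged sets, that stage indices
#' are distinct and consecutive starting at 1.
#'
#' @param sets named list of \code{\link{region_set}} objects.
#' @param catalog a \code{\link{region_catalog}}.
#' @return the validated list, invisibly ordered with staged sets first by
#'   stage index.
#' @export
validate_region_sets <- function(sets, catalog) {
  for (s in sets) {
    missing <- setdiff(s$region_ids, catalog$region_id)
    if (length(missing))
      stop("region set '", s$name, "' references unknown regions: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  idx <- vapply(sets, function(s) s$stage_index, integer(1))
  staged <- sort(idx[!is.na(idx)])
  if (length(staged) && !identical(as.integer(staged), seq_along(staged)))
    stop("staged region sets must carry distinct consecutive stage indices ",
         "starting at 1; got ", paste(staged, collapse = ", "))
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

staged_sets_of <- function(sets) {
  staged <- Filter(function(s) !is.na(s$stage_index), sets)
  staged[order(vapply(staged, `[[`, integer(1), "stage_index"))]
}

#' Write region sets to JSON
#'
#' @param sets named list of \code{\link{region_set}} objects.
#' @param path output file path.
#' @export
write_region_sets <- function(sets, path) {
  obj <- lapply(sets, function(s) {
    rec <- list(region_ids = s$region_ids)
    if (!is.na(s$stage_index)) rec$stage_index <- s$stage_index
    rec
  })
  names(obj) <- vapply(sets, `[[`, character(1), "name")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read region sets from JSON
#'
#' @param path JSON file mapping set name to \code{{region_ids, stage_index}}.
#' @param catalog optional catalog for validation.
#' @return named list of \code{\link{region_set}} objects.
#' @export
read_region_sets <- function(path, catalog = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- lapply(names(obj), function(nm) {
    rec <- obj[[nm]]
    region_set(nm, rec$region_ids,
               if (is.null(rec$stage_index)) NA_integer_ else rec$stage_index)
  })
  names(sets) <- names(obj)
  if (!is.null(catalog)) sets <- validate_region_sets(sets, catalog)
  sets
}
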