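#' Construct a voxel block
#'
#' Voxel-level SUVR for one subject-timepoint: parallel arrays of voxel
#' SUVR, region labels and a gray-matter mask. The voxel ordering must be
#' identical across a subject's timepoints.
#'
#' @param subject_id subject identifier.
#' @param timepoint "baseline" or "followup".
#' @param voxel_suvr numeric vector of voxel SUVR values.
#' @param voxel_region character vector of region ids, parallel to
#'   \code{voxel_suvr}.
#' @param gm_mask logical vector, parallel; masked-in voxels must carry
#'   finite positive SUVR.
#' @return list of class \code{voxel_block}.
#' @export
voxel_block <- function(subject_id, timepoint, voxel_suvr, voxel_region,
                        gm_mask = rep(TRUE, length(voxel_suvr))) {
  n <- length(voxel_suvr)
  if (length(voxel_region) != n || length(gm_mask) != n)
    stop("voxel_block: arrays must have equal length")
  if (any(!is.finite(voxel_suvr[gm_mask]) | voxel_suvr[gm_mask] <= 0))
    stop("voxel_block: masked-in voxels must have finite positive SUVR")
  structure(list(subject_id = subject_id, timepoint = timepoint,
                 voxel_suvr = as.numeric(voxel_suvr),
                 voxel_region = as.character(voxel_region),
                 gm_mask = as.logical(gm_mask)),
            class = "voxel_block")
}

#' Write a voxel block to TSV
#' @param vb a \code{\link{voxel_block}}.
#' @param path output path.
#' @export
write_voxel_block <- function(vb, path) {
  df <- data.frame(subject_id = vb$subject_id, timepoint = vb$timepoint,
                   voxel_suvr = vb$voxel_suvr,
                   voxel_region = vb$voxel_region, gm_mask = vb$gm_mask,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a voxel block from TSV
#' @param path TSV written by \code{\link{write_voxel_block}}.
#' @return a \code{\link{voxel_block}}.
#' @export
read_voxel_block <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  voxel_block(df$subject_id[1], df$timepoint[1], df$voxel_suvr,
              df$voxel_region, df$gm_mask)
}

#' Read a voxel block from NIfTI images
#'
#' Optional reader for volumetric inputs: an SUVR image, an integer label
#' image (indices into \code{region_ids}, 0 = background) and a binary
#' gray-matter mask image, all on the same grid. Requires the RNifti
#' package. Background voxels (label 0) are dropped.
#'
#' @param suvr_path,label_path,mask_path NIfTI file paths.
#' @param region_ids character vector mapping label values 1..K to region
#'   ids.
#' @param subject_id,timepoint recorded in the block.
#' @return a \code{\link{voxel_block}}.
#' @export
read_voxel_block_nifti <- function(suvr_path, label_path, mask_path,
                                   region_ids, subject_id,
                                   timepoint = "baseline") {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_voxel_block_nifti requires the RNifti package")
  suvr <- as.numeric(RNifti::readNifti(suvr_path))
  lab <- as.integer(RNifti::readNifti(label_path))
  mask <- as.numeric(RNifti::readNifti(mask_path)) > 0
  keep <- lab > 0
  voxel_block(subject_id, timepoint, suvr[keep], region_ids[lab[keep]],
              mask[keep])
}

#' Restrict a voxel block to an ROI
#'
#' @param vb a \code{\link{voxel_block}}.
#' @param region_ids regions to keep (ignored if \code{mask} given).
#' @param mask optional logical voxel mask (e.g. from the overlap method).
#' @param gm_only additionally restrict to the gray-matter mask.
#' @return a \code{\link{voxel_block}} containing only the selected voxels.
#' @export
subset_voxel_block <- function(vb, region_ids = NULL, mask = NULL,
                               gm_only = TRUE) {
  keep <- rep(TRUE, length(vb$voxel_suvr))
  if (!is.null(region_ids)) keep <- keep & vb$voxel_region %in% region_ids
  if (!is.null(mask)) keep <- keep & mask
  if (gm_only) keep <- keep & vb$gm_mask
  if (!any(keep)) stop("subset_voxel_block: no voxels selected")
  voxel_block(vb$subject_id, vb$timepoint, vb$voxel_suvr[keep],
              vb$voxel_region[keep], vb$gm_mask[keep])
}
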