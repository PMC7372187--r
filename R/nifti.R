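#' Voxelwise features from 3D volumes and a binary mask
#'
#' Builds a subject-by-voxel feature matrix (e.g. FA or GMV) from one
#' NIfTI volume per subject and a binary mask. The mask defines the
#' feature order: ascending linear index within the volume array
#' (x-fastest), which is R's native array order.
#'
#' Requires the RNifti package.
#'
#' @param files character vector of per-subject NIfTI volume paths.
#' @param mask_file NIfTI binary mask path (nonzero = in-mask).
#' @param modality label for the resulting features.
#' @param subject_ids optional labels; defaults to file base names.
#' @return a \code{\link{modality_features}} plus a \code{"mask"}
#'   attribute holding the mask array (for later export).
#' @export
read_nifti_features <- function(files, mask_file, modality,
                                subject_ids = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required for NIfTI input")
  mask <- as.array(RNifti::readNifti(mask_file)) != 0
  idx <- which(mask)
  if (!length(idx)) stopf("mask is empty")
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
  X <- t(vapply(files, function(fp) {
    vol <- as.array(RNifti::readNifti(fp))
    if (!identical(dim(vol), dim(mask)))
      stopf("volume %s does not match mask dimensions", basename(fp))
    as.numeric(vol[idx])
  }, numeric(length(idx))))
  out <- modality_features(modality, X,
                           feature_ids = sprintf("vox%07d", idx),
                           subject_ids = subject_ids)
  attr(out, "mask") <- mask
  out
}

#' Export a feature-space map back into a masked NIfTI volume
#'
#' @param map numeric vector over in-mask voxels (mask order).
#' @param mask logical/0-1 array defining the voxel order (as stored by
#'   \code{\link{read_nifti_features}}).
#' @param file output .nii path.
#' @return \code{file}, invisibly.
#' @export
export_nifti_map <- function(map, mask, file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required for NIfTI export")
  mask <- as.array(mask) != 0
  if (sum(mask) != length(map))
    stopf("map length %d does not match mask voxel count %d",
          length(map), sum(mask))
  vol <- array(0, dim = dim(mask))
  vol[which(mask)] <- map
  RNifti::writeNifti(RNifti::asNifti(vol), file)
  invisible(file)
}
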