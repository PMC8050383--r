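# NIfTI I/O via RNifti. NIfTI affines map voxel indices to RAS
# (right-anterior-superior); internally everything is LPS (DICOM), so the
# first two affine rows are negated on load and save.

ras_to_lps <- diag(c(-1, -1, 1))

#' Read a CT volume
#'
#' Loads a CT series from a DICOM directory or a NIfTI file into a
#' [ct_volume()] with intensities in HU and geometry (spacing, origin,
#' direction cosines) in the LPS patient frame, axes ordered (x, y, z).
#'
#' @param path a NIfTI file (`.nii`/`.nii.gz`) or a directory of DICOM
#'   slices.
#' @param format `"nifti"`, `"dicom_series"`, or `NULL` to infer from
#'   `path`.
#' @return A `ct_volume`.
#' @export
read_ct_volume <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  switch(format,
    nifti = read_ct_nifti(path),
    dicom_series = read_dicom_series(path),
    stopf("unsupported CT format '%s'", format)
  )
}

read_ct_nifti <- function(path) {
  if (!file.exists(path)) stopf("NIfTI file not found: %s", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img) # voxel (0-based) -> RAS
  A <- ras_to_lps %*% aff[1:3, 1:3]
  origin <- as.numeric(ras_to_lps %*% aff[1:3, 4])
  spacing <- sqrt(colSums(A^2))
  orientation <- sweep(A, 2, spacing, `/`)
  vox <- array(as.numeric(img), dim(img)[1:3])
  ct_volume(vox, spacing = spacing, origin = origin, orientation = orientation)
}

#' Write a CT volume (or mask) as NIfTI
#'
#' @param volume a `ct_volume` or `binary_mask` (written as 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  if (inherits(volume, "binary_mask")) {
    arr <- array(as.integer(volume$occupancy), dim(volume$occupancy))
    g <- volume
  } else {
    stopifnot(inherits(volume, "ct_volume"))
    arr <- volume$voxels
    g <- volume
  }
  A_lps <- g$orientation %*% diag(g$spacing)
  aff <- rbind(cbind(ras_to_lps %*% A_lps, as.numeric(ras_to_lps %*% g$origin)),
               c(0, 0, 0, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- g$spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Voxels greater than 0.5 are foreground.
#'
#' @param path NIfTI file.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path) {
  vol <- read_ct_nifti(path)
  binary_mask(vol$voxels > 0.5, grid = vol)
}
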