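#' CT volume with physical geometry
#'
#' A calibrated CT intensity grid (Hounsfield units) together with its
#' physical geometry: per-axis voxel size, the patient-space position of the
#' center of voxel (1,1,1), and a direction-cosine matrix. All geometry is in
#' millimetres in the LPS (left-posterior-superior, DICOM) patient frame;
#' NIfTI input, which is RAS by convention, is converted on load so every
#' downstream computation lives in a single frame. Voxel coordinates are
#' cell-centered: the world position of (1-based) index `i` is
#' `origin + orientation %*% ((i - 1) * spacing)`.
#'
#' @param voxels 3D numeric array of intensities in HU, axes (x, y, z).
#' @param spacing length-3 positive numeric, voxel size in mm per axis.
#' @param origin length-3 numeric, world position (mm) of voxel (1,1,1).
#' @param orientation 3x3 direction-cosine matrix (orthonormal columns).
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 4)), spacing = c(0.6, 0.6, 0.6))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(0.6, 0.6, 0.6),
                      origin = c(0, 0, 0), orientation = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("origin must be 3 finite numbers (mm)")
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stopf("orientation must have orthonormal columns")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%s) mm\n",
              min(x$voxels), max(x$voxels),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

# world coordinates (n x 3) of 1-based voxel indices (n x 3 matrix)
grid_to_world <- function(grid, index) {
  idx <- sweep(index - 1, 2, grid$spacing, `*`)
  sweep(idx %*% t(grid$orientation), 2, grid$origin, `+`)
}

grid_geometry <- function(x) {
  list(dim = dim(x$voxels %||% x$occupancy), spacing = x$spacing,
       origin = x$origin, orientation = x$orientation)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_geometry(a); gb <- grid_geometry(b)
  identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol &&
    max(abs(ga$orientation - gb$orientation)) <= tol
}
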