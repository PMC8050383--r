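#' Binary voxel mask on a CT grid
#'
#' Voxel occupancy sharing the geometry of the CT volume it was derived
#' from. The mask volume is the number of occupied voxels multiplied by the
#' voxel volume.
#'
#' @param occupancy 3D logical array.
#' @param grid a `ct_volume` (or another `binary_mask`) supplying the
#'   geometry, or `NULL` with explicit `spacing`/`origin`/`orientation`.
#' @param spacing,origin,orientation geometry, used when `grid` is `NULL`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(occupancy, grid = NULL, spacing = c(0.6, 0.6, 0.6),
                        origin = c(0, 0, 0), orientation = diag(3)) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    stopf("occupancy must be a 3D array")
  storage.mode(occupancy) <- "logical"
  if (!is.null(grid)) {
    g <- grid_geometry(grid)
    if (!identical(dim(occupancy), as.integer(g$dim)))
      stopf("mask shape %s does not match grid shape %s",
            paste(dim(occupancy), collapse = "x"), paste(g$dim, collapse = "x"))
    spacing <- g$spacing; origin <- g$origin; orientation <- g$orientation
  }
  structure(list(occupancy = occupancy, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 orientation = matrix(as.numeric(orientation), 3, 3)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<binary_mask> %d x %d x %d, %d voxels set, volume %.2f mm^3\n",
              d[1], d[2], d[3], sum(x$occupancy), mask_volume(x)))
  invisible(x)
}

#' Volume enclosed by a binary mask
#'
#' Occupied-voxel count multiplied by the voxel volume, in mm^3. Invariant
#' under any change of the grid origin or orientation.
#'
#' @param mask a `binary_mask`.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$occupancy) * prod(mask$spacing)
}

#' Threshold a CT volume into a binary mask
#'
#' Voxels with `lo <= HU <= hi` become occupied. This is the first
#' segmentation step separating bone (or cement) from soft tissue. Widening
#' the HU window never removes voxels.
#'
#' @param volume a `ct_volume`.
#' @param lo,hi HU bounds, `lo < hi` (use `Inf` for an unbounded top).
#' @return A `binary_mask` on the volume's grid (possibly empty).
#' @examples
#' vol <- ct_volume(array(1000, c(3, 3, 3)))
#' sum(threshold_mask(vol, 200, 2000)$occupancy)
#' @export
threshold_mask <- function(volume, lo, hi = Inf) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.numeric(lo) || !is.numeric(hi) || !(lo < hi))
    stopf("thresholds must satisfy lo < hi (got lo=%s, hi=%s)", lo, hi)
  occ <- volume$voxels >= lo & volume$voxels <= hi
  binary_mask(occ, grid = volume)
}

#' Fill internal cavities of a mask
#'
#' Background voxels not connected to the array border become foreground,
#' preserving the outer contour. The default `per_slice` mode fills within
#' each axial (x, y) slice in 2D; `"3d"` fills volumetrically. Filling is
#' idempotent and never removes voxels.
#'
#' @param mask a nonempty `binary_mask`.
#' @param mode `"per_slice"` (default) or `"3d"`.
#' @return The filled `binary_mask`.
#' @export
fill_mask <- function(mask, mode = c("per_slice", "3d")) {
  stopifnot(inherits(mask, "binary_mask"))
  mode <- match.arg(mode)
  if (!any(mask$occupancy)) stopf("cannot fill an empty mask")
  filled <- fill_holes_cpp(mask$occupancy, mode == "per_slice")
  binary_mask(filled, grid = mask)
}

#' Keep only the largest connected component
#'
#' Isolates one body (a vertebra, the cement) from thresholding debris.
#' Ties in size are broken in favour of the component whose seed has the
#' lowest linear voxel index.
#'
#' @param mask a nonempty `binary_mask`.
#' @param connectivity 6 (face) or 26 (face/edge/corner) neighbourhood.
#' @return A `binary_mask` containing one component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  comps <- split_components(mask, connectivity)
  comps[[1]]
}

# all components as masks, ordered by decreasing size (ties: first-seen label)
split_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6, 26)) stopf("connectivity must be 6 or 26")
  if (!any(mask$occupancy)) stopf("cannot label an empty mask")
  lab <- label_components_cpp(mask$occupancy, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L], nbins = attr(lab, "n_components"))
  ord <- order(-sizes, seq_along(sizes))
  lapply(ord, function(l) binary_mask(array(lab == l, dim(lab)), grid = mask))
}

#' Dice similarity index of two segmentations
#'
#' `DSI = 2 V(I1 and I2) / (V(I1) + V(I2))`, the relative volume overlap of
#' two binary masks, where V is the occupied-voxel count times the voxel
#' volume. 1 is a perfect match, 0 complete disjointness. The masks must
#' live on identical grids; resample first (see [resample_mask()]) when
#' they come from different sessions.
#'
#' @param mask1,mask2 `binary_mask` objects on the same grid.
#' @return DSI in `[0, 1]`.
#' @export
dice_similarity <- function(mask1, mask2) {
  stopifnot(inherits(mask1, "binary_mask"), inherits(mask2, "binary_mask"))
  if (!same_grid(mask1, mask2))
    stopf("masks are on different grids; resample_mask() one onto the other first")
  n1 <- sum(mask1$occupancy)
  n2 <- sum(mask2$occupancy)
  if (n1 == 0L && n2 == 0L) stopf("DSI undefined: both masks are empty")
  2 * sum(mask1$occupancy & mask2$occupancy) / (n1 + n2)
}

#' Resample a mask onto another grid (nearest neighbour)
#'
#' Maps each voxel center of the target grid into the source mask's index
#' space and takes the nearest voxel; outside voxels are background.
#'
#' @param mask source `binary_mask`.
#' @param grid a `ct_volume` or `binary_mask` defining the target geometry.
#' @return A `binary_mask` on the target grid.
#' @export
resample_mask <- function(mask, grid) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- grid_geometry(grid)
  d <- as.integer(g$dim)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3])))
  world <- grid_to_world(g, idx)
  # into source index space
  rel <- sweep(world, 2, mask$origin, `-`) %*% mask$orientation
  src <- round(sweep(rel, 2, mask$spacing, `/`)) + 1
  ds <- dim(mask$occupancy)
  ok <- src[, 1] >= 1 & src[, 1] <= ds[1] &
        src[, 2] >= 1 & src[, 2] <= ds[2] &
        src[, 3] >= 1 & src[, 3] <= ds[3]
  occ <- logical(nrow(src))
  occ[ok] <- mask$occupancy[cbind(src[ok, 1], src[ok, 2], src[ok, 3])]
  binary_mask(array(occ, d), spacing = g$spacing, origin = g$origin,
              orientation = g$orientation)
}

#' Segment a structure from a CT volume
#'
#' Convenience wrapper running the canonical mask pipeline: HU thresholding,
#' cavity filling, and largest-component extraction. The HU window used is
#' recorded in the result for provenance. Defaults follow common CT presets:
#' a 226 HU lower bound for bone; PMMA cement is much denser (use
#' `lo = 1500`).
#'
#' @param volume a `ct_volume`.
#' @param lo,hi HU window.
#' @param fill `"per_slice"`, `"3d"`, or `"none"`.
#' @param keep_largest keep only the largest connected component.
#' @param label free-text label stored with the result.
#' @return A `segmentation_result`: list with `mask`, `threshold_lo`,
#'   `threshold_hi`, `label`.
#' @export
segment_structure <- function(volume, lo = 226, hi = Inf,
                              fill = c("per_slice", "3d", "none"),
                              keep_largest = TRUE, label = "vertebra") {
  fill <- match.arg(fill)
  mask <- threshold_mask(volume, lo, hi)
  if (!any(mask$occupancy))
    stopf("segmentation produced an empty mask (window [%g, %g] HU)", lo, hi)
  if (keep_largest) mask <- largest_component(mask)
  if (fill != "none") mask <- fill_mask(mask, mode = fill)
  structure(list(mask = mask, threshold_lo = lo, threshold_hi = hi, label = label),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> '%s', HU window [%g, %g]\n",
              x$label, x$threshold_lo, x$threshold_hi))
  print(x$mask)
  invisible(x)
}
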