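#' Ordered anatomical landmark set
#'
#' Named, ordered control points (mm) picked on easily identifiable
#' anatomical features of the caudal vertebra. Two sets are comparable only
#' when their names appear in identical order; the clinical protocol uses 18
#' points.
#'
#' @param points n x 3 numeric matrix of coordinates (mm).
#' @param names character vector of unique landmark names.
#' @param frame `"preop"` or `"postop"` (or any frame label).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, names = NULL, frame = "preop") {
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(names)) names <- sprintf("P%02d", seq_len(nrow(points)))
  names <- as.character(names)
  if (length(names) != nrow(points)) stopf("one name per landmark required")
  if (anyDuplicated(names)) stopf("duplicate landmark names: %s",
                                  paste(unique(names[duplicated(names)]), collapse = ", "))
  rownames(points) <- names
  structure(list(points = points, frame = frame), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points, frame '%s'\n", nrow(x$points), x$frame))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' A proper rigid motion `x -> R x + t`: `R` is orthonormal with
#' determinant +1 (no reflection, no scaling), `t` in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stopf("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%s) mm\n",
              ang, paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

#' Rotation angle of a rigid transform
#' @param transform a `rigid_transform`.
#' @return Angle in radians.
#' @export
rotation_angle <- function(transform) {
  acos(min(1, max(-1, (sum(diag(transform$rotation)) - 1) / 2)))
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -Rt %*% transform$translation)
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform` objects; the result applies `b` first.
#' @return `rigid_transform` equal to `a(b(x))`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to points, a mesh, or a landmark set
#'
#' Maps vertices by `R x + t`; faces and topology are unchanged, and the
#' enclosed volume is invariant (rigid motions preserve volume).
#'
#' @param x a `surface_mesh`, `landmark_set`, or n x 3 matrix.
#' @param transform a `rigid_transform`.
#' @return The transformed object.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  map <- function(p) sweep(p %*% t(transform$rotation), 2, transform$translation, `+`)
  if (inherits(x, "surface_mesh")) {
    surface_mesh(map(x$vertices), x$faces)
  } else if (inherits(x, "landmark_set")) {
    landmark_set(map(x$points), rownames(x$points), x$frame)
  } else {
    map(matrix(as.numeric(x), ncol = 3))
  }
}

#' Least-squares rigid registration of corresponding landmarks
#'
#' Closed-form Kabsch/Procrustes fit via SVD with a reflection guard:
#' returns the proper rigid transform `T` minimising
#' `sum_i || T(moving_i) - fixed_i ||^2` over rotations with det +1 and
#' translations (no scaling). Landmarks correspond by name and order; at
#' least 3 non-collinear points are required.
#'
#' @param moving,fixed `landmark_set` objects with identical names in
#'   identical order (e.g. preoperative and postoperative picks).
#' @return A `rigid_transform` with attribute `rms` (root-mean-square
#'   residual, mm).
#' @export
fit_rigid_landmarks <- function(moving, fixed) {
  stopifnot(inherits(moving, "landmark_set"), inherits(fixed, "landmark_set"))
  if (!identical(rownames(moving$points), rownames(fixed$points)))
    stopf("landmark names/order differ between the two sets")
  M <- moving$points
  X <- fixed$points
  n <- nrow(M)
  if (n < 3) stopf("at least 3 landmarks are required (got %d)", n)
  cm <- colMeans(M)
  cf <- colMeans(X)
  A <- sweep(M, 2, cm)
  B <- sweep(X, 2, cf)
  # collinearity check: rank of the centered moving cloud
  sv <- svd(A)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stopf("landmarks are collinear; the rotation is not identifiable")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tv <- cf - as.numeric(Rm %*% cm)
  tr <- rigid_transform(Rm, tv)
  res <- apply_transform(M, tr) - X
  attr(tr, "rms") <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Hausdorff distance between two meshes
#'
#' Vertex-to-vertex point-set distance: for every vertex `a` of `A`, the
#' minimum Euclidean distance to the vertices of `B`;
#' `h(A,B) = max_a min_b d(a,b)`. Zero for a perfect alignment of identical
#' geometries. `one_sided` uses A -> B only (convention: A = postoperative
#' mesh, B = preoperative reference); `symmetric` returns
#' `max(h(A,B), h(B,A))`.
#'
#' @param A,B `surface_mesh` objects (nonempty vertex sets).
#' @param mode `"one_sided"` or `"symmetric"`.
#' @return List with `max` (mm) and `per_vertex` (distances for the
#'   vertices of `A`; in symmetric mode also `per_vertex_ba`).
#' @export
hausdorff_distance <- function(A, B, mode = c("one_sided", "symmetric")) {
  mode <- match.arg(mode)
  stopifnot(inherits(A, "surface_mesh"), inherits(B, "surface_mesh"))
  if (nrow(A$vertices) == 0L || nrow(B$vertices) == 0L)
    stopf("empty vertex set")
  dab <- nn_distances_cpp(A$vertices, B$vertices)
  if (mode == "one_sided")
    return(list(max = max(dab), per_vertex = dab))
  dba <- nn_distances_cpp(B$vertices, A$vertices)
  list(max = max(max(dab), max(dba)), per_vertex = dab, per_vertex_ba = dba)
}

#' Empirical CDF of per-vertex distances
#'
#' The cumulative-probability view of an alignment's per-vertex distances:
#' monotone nondecreasing and ending at 1.
#'
#' @param per_vertex numeric vector of distances (mm).
#' @return data.frame with columns `distance` and `cumulative_fraction`.
#' @export
distance_cdf <- function(per_vertex) {
  if (length(per_vertex) == 0L) stopf("no distances supplied")
  d <- sort(unique(per_vertex))
  frac <- vapply(d, function(x) mean(per_vertex <= x), numeric(1))
  data.frame(distance = d, cumulative_fraction = frac)
}

#' Alignment quality report
#'
#' Bundles the fitted transform, landmark residual, and Hausdorff metrics
#' of a pre-to-post alignment.
#'
#' @param transform fitted `rigid_transform`.
#' @param moving_mesh,fixed_mesh aligned (moving already transformed) and
#'   reference `surface_mesh` (typically the caudal vertebra).
#' @return An `alignment_report`: transform, `landmark_rms`,
#'   `hausdorff_one_sided`, `hausdorff_symmetric`, `per_vertex_distances`.
#' @export
alignment_report <- function(transform, moving_mesh, fixed_mesh) {
  hd <- hausdorff_distance(fixed_mesh, moving_mesh, mode = "symmetric")
  structure(list(transform = transform,
                 landmark_rms = attr(transform, "rms") %||% NA_real_,
                 hausdorff_one_sided = max(hd$per_vertex),
                 hausdorff_symmetric = hd$max,
                 per_vertex_distances = hd$per_vertex),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> landmark RMS %.4g mm, HD %.4g mm (symmetric %.4g mm)\n",
              x$landmark_rms, x$hausdorff_one_sided, x$hausdorff_symmetric))
  invisible(x)
}
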