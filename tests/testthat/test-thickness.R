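test_that("parallel plates report the wall separation", {
  # closed 20 x 20 x 5 box: the two large faces see 5 mm walls
  occ <- array(FALSE, c(26, 26, 11))
  occ[4:23, 4:23, 4:8] <- TRUE
  box <- mask_to_mesh(binary_mask(occ, spacing = c(1, 1, 1)))
  tm <- thickness_map(box)
  ctr <- (box$vertices[box$faces[, 1], ] + box$vertices[box$faces[, 2], ] +
            box$vertices[box$faces[, 3], ]) / 3
  plate <- abs(ctr[, 1] - 12.5) < 6 & abs(ctr[, 2] - 12.5) < 6 &
    (abs(ctr[, 3] - 2.5) < 0.2 | abs(ctr[, 3] - 7.5) < 0.2)
  expect_true(all(abs(tm$values[plate] - 5) < 1e-6))
  expect_identical(length(tm$values), nrow(box$faces))
})

test_that("a spherical shell reports the radial wall thickness", {
  # smoothed first, as the protocol measures thickness on smoothed surfaces;
  # raw voxel meshes have oblique face normals that lengthen the ray
  shell <- smooth_mesh(mask_to_mesh(shell_mask(outer = 10, inner = 8, spacing = 0.4)),
                       iterations = 3, factor = 0.7)
  tm <- thickness_map(shell)
  ctr <- (shell$vertices[shell$faces[, 1], ] + shell$vertices[shell$faces[, 2], ] +
            shell$vertices[shell$faces[, 3], ]) / 3
  cen <- colMeans(shell$vertices)
  rr <- sqrt(rowSums(sweep(ctr, 2, cen)^2))
  outer_faces <- rr > 9
  expect_equal(mean(tm$values[outer_faces], na.rm = TRUE), 2, tolerance = 0.05)
})

test_that("thickness hits equal the exhaustive ray-intersection oracle", {
  mesh <- mask_to_mesh(ball_mask(r = 3, spacing = 1))
  tm <- thickness_map(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  mt_hit <- function(o, d, a, b, c) { # Moller-Trumbore, same tolerances
    e1 <- b - a; e2 <- c - a
    p <- c(d[2] * e2[3] - d[3] * e2[2], d[3] * e2[1] - d[1] * e2[3],
           d[1] * e2[2] - d[2] * e2[1])
    det <- sum(e1 * p)
    if (abs(det) < 1e-14) return(NA_real_)
    tvec <- o - a
    u <- sum(tvec * p) / det
    if (u < -1e-12 || u > 1 + 1e-12) return(NA_real_)
    q <- c(tvec[2] * e1[3] - tvec[3] * e1[2], tvec[3] * e1[1] - tvec[1] * e1[3],
           tvec[1] * e1[2] - tvec[2] * e1[1])
    w <- sum(d * q) / det
    if (w < -1e-12 || u + w > 1 + 1e-12) return(NA_real_)
    t <- sum(e2 * q) / det
    if (t > 1e-6) t else NA_real_
  }
  for (f in sample(seq_len(nrow(F)), 25)) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c3 <- V[F[f, 3], ]
    n <- c((b - a)[2] * (c3 - a)[3] - (b - a)[3] * (c3 - a)[2],
           (b - a)[3] * (c3 - a)[1] - (b - a)[1] * (c3 - a)[3],
           (b - a)[1] * (c3 - a)[2] - (b - a)[2] * (c3 - a)[1])
    n <- n / sqrt(sum(n^2))
    o <- (a + b + c3) / 3
    best <- Inf
    for (g in seq_len(nrow(F))) {
      if (g == f || any(F[g, ] %in% F[f, ])) next
      t <- mt_hit(o, -n, V[F[g, 1], ], V[F[g, 2], ], V[F[g, 3], ])
      if (!is.na(t) && t < best) best <- t
    }
    expect_equal(tm$values[f], if (is.finite(best)) best else NA_real_,
                 tolerance = 1e-9)
  }
})

test_that("thickness is everywhere defined on convex solids and scales linearly", {
  ball <- mask_to_mesh(ball_mask(r = 5, spacing = 0.8))
  tm <- thickness_map(ball)
  expect_identical(tm$stats$fraction_defined, 1)
  doubled <- surface_mesh(ball$vertices * 2, ball$faces)
  tm2 <- thickness_map(doubled)
  expect_equal(tm2$values, tm$values * 2, tolerance = 1e-9)
})

test_that("geometry summaries combine volume, area and thickness", {
  cube <- cube_mesh()
  s <- summarize_geometry(cube)
  expect_identical(s$volume_mm3, 1)
  expect_identical(s$area_mm2, 6)
  expect_equal(s$thickness$min, 1, tolerance = 1e-9)
  expect_equal(s$thickness$max, 1, tolerance = 1e-9)

  # degenerate zero-area faces are skipped with a warning: split one edge of
  # a cube face and stitch the cut with a collinear sliver triangle, which
  # keeps the mesh watertight
  v <- rbind(cube$vertices, c(0.5, 0, 0)) # midpoint of the edge 1-2
  f <- cube$faces[-5, ]                    # drop face (1,2,6)
  f <- rbind(f, c(1, 9, 6), c(9, 2, 6), c(2, 9, 1))
  degen <- surface_mesh(v, f)
  expect_true(is_watertight(degen))
  expect_warning(tm <- thickness_map(degen), "zero-area")
  expect_true(is.na(tm$values[nrow(f)]))
})

test_that("thickness maps export as PLY face quality and CSV", {
  cube <- cube_mesh()
  tm <- thickness_map(cube)
  fp <- withr::local_tempfile(fileext = ".ply")
  write_thickness(tm, fp)
  back <- read_mesh(fp)
  expect_equal(attr(back, "face_scalar"), tm$values, tolerance = 1e-12)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_thickness(tm, fc)
  df <- read.csv(fc)
  expect_identical(nrow(df), 12L)
  expect_equal(df$thickness_mm, tm$values, tolerance = 1e-12)
})
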