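test_that("mask_to_mesh reproduces analytic and voxel-count volumes", {
  ball <- ball_mask(r = 10, spacing = 0.6)
  m <- mask_to_mesh(ball)
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 4 / 3 * pi * 1000, tolerance = 0.02)
  expect_equal(mesh_volume(m), mask_volume(ball), tolerance = 0.02)

  # grid convergence towards the voxel-count volume
  fine <- ball_mask(r = 10, spacing = 0.3)
  mf <- mask_to_mesh(fine)
  err_coarse <- abs(mesh_volume(m) / mask_volume(ball) - 1)
  err_fine <- abs(mesh_volume(mf) / mask_volume(fine) - 1)
  expect_lt(err_fine, err_coarse + 1e-9)

  # single voxel still yields a closed surface of roughly one voxel volume
  occ <- array(FALSE, c(5, 5, 5)); occ[3, 3, 3] <- TRUE
  sv <- mask_to_mesh(binary_mask(occ, spacing = c(1, 1, 1)))
  expect_true(is_watertight(sv))
  expect_gt(mesh_volume(sv), 0.5)
  expect_lt(mesh_volume(sv), 1.5)

  expect_error(mask_to_mesh(binary_mask(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("volume_to_mesh places surfaces at the iso level with sub-voxel accuracy", {
  n <- 40; sp <- 0.6
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  w <- sweep(idx - 1, 2, rep(sp, 3), `*`)
  nrm <- c(sin(4 * pi / 180), 0, cos(4 * pi / 180))
  d <- (w %*% nrm) - 11
  v <- pmin(pmax(0.5 - d / sp, 0), 1) # partial-volume ramp of a tilted halfspace
  m <- volume_to_mesh(ct_volume(array(v, c(n, n, n)), spacing = rep(sp, 3)), 0.5)
  vd <- (m$vertices %*% nrm) - 11
  core <- abs(vd) < 2 & m$vertices[, 1] > 3 & m$vertices[, 1] < 20 &
    m$vertices[, 2] > 3 & m$vertices[, 2] < 20
  expect_lt(max(abs(vd[core])), 0.08)
  expect_true(is_watertight(m))
})

test_that("smoothing conserves volume with compensation and reduces roughness", {
  ball <- mask_to_mesh(ball_mask(r = 10, spacing = 0.6))
  expect_identical(smooth_mesh(ball, iterations = 0), ball)

  set.seed(31)
  ctr <- colMeans(ball$vertices)
  rel <- sweep(ball$vertices, 2, ctr)
  rr <- sqrt(rowSums(rel^2))
  noisy <- surface_mesh(sweep(rel * (1 + rnorm(length(rr), 0, 0.03)), 2, ctr, `+`),
                        ball$faces)
  v0 <- mesh_volume(noisy)
  sm <- smooth_mesh(noisy, iterations = 6, factor = 0.7, compensate_shrinkage = TRUE)
  expect_identical(dim(sm$vertices), dim(noisy$vertices))
  expect_identical(sm$faces, noisy$faces)
  expect_equal(mesh_volume(sm), v0, tolerance = 0.005)
  cv <- function(mm) {
    r <- sqrt(rowSums(sweep(mm$vertices, 2, colMeans(mm$vertices))^2))
    sd(r) / mean(r)
  }
  expect_lt(cv(sm), cv(noisy))

  # without compensation a cube shrinks; with compensation it does not
  cube <- cube_mesh(side = 10)
  off <- smooth_mesh(cube, 6, 0.7, compensate_shrinkage = FALSE)
  on <- smooth_mesh(cube, 6, 0.7, compensate_shrinkage = TRUE)
  expect_lt(mesh_volume(off), 1000 * 0.9)
  expect_equal(mesh_volume(on), 1000, tolerance = 0.005)

  open <- surface_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(smooth_mesh(open, 6, 0.7, TRUE), "watertight")
})

test_that("uniform remeshing hits the target edge length and keeps features", {
  cube <- cube_mesh(side = 20)
  rm <- remesh_uniform(cube, remesh_params(target_edge = 2))
  expect_true(is_watertight(rm))
  expect_equal(mesh_volume(rm), 8000, tolerance = 0.01)
  expect_equal(median(edge_lengths(rm)), 2, tolerance = 0.25)
  fe <- feature_edges(rm, 60)
  expect_gt(nrow(fe), 0)
  # every feature edge lies on one of the 12 cube edges; all 12 survive
  lines <- unique(t(apply(fe, 1, function(e) {
    a <- rm$vertices[e[1], ]; b <- rm$vertices[e[2], ]
    ax <- which.max(abs(a - b))
    c(ax, round(a[-ax], 6))
  })))
  expect_identical(nrow(lines), 12L)
  on_edges <- apply(fe, 1, function(e) {
    p <- rm$vertices[c(e[1], e[2]), ]
    all(vapply(1:2, function(r) sum(abs(p[r, ]) < 1e-6 | abs(p[r, ] - 20) < 1e-6) >= 2,
               logical(1)))
  })
  expect_true(all(on_edges))

  # near target density already: volume and area nearly unchanged
  sph <- icosphere(r = 10, subdivisions = 3)
  rb <- remesh_uniform(sph, remesh_params(target_edge = median(edge_lengths(sph))))
  expect_equal(mesh_volume(rb), mesh_volume(sph), tolerance = 0.01)
  expect_equal(mesh_area(rb), mesh_area(sph), tolerance = 0.01)

  expect_error(remesh_uniform(cube, remesh_params(target_edge = 15)), "too coarse")
})

test_that("mesh volume and area match closed-form values and flag bad meshes", {
  cube <- cube_mesh()
  expect_identical(mesh_volume(cube), 1)
  expect_identical(mesh_area(cube), 6)

  cyl <- make_cylinder(c(0, 0, 0), c(0, 0, 1), length = 90, radius = 10,
                       n_segments = 256)
  expect_equal(mesh_volume(cyl$mesh), pi * 100 * 90, tolerance = 0.005)

  flipped <- cube
  flipped$faces[1, ] <- flipped$faces[1, c(1, 3, 2)]
  expect_error(mesh_volume(flipped), "watertight")
  open <- surface_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_volume(open), "watertight")
  expect_equal(mesh_area(open), 5.5) # area remains defined
})
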