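test_that("measurement cylinders match their analytic volume", {
  c10 <- make_cylinder(c(0, 0, 0), c(1, 0, 0), length = 90, radius = 10)
  expect_equal(c10$volume, 28274.334, tolerance = 1e-6)
  expect_equal(mesh_volume(c10$mesh), c10$volume, tolerance = 0.002)
  expect_true(is_watertight(c10$mesh))

  c12 <- make_cylinder(c(5, -3, 2), c(1, 1, 0), length = 90, radius = 12)
  expect_equal(c12$volume, 40715.041, tolerance = 1e-6)
  expect_equal(mesh_volume(c12$mesh), c12$volume, tolerance = 0.002)
  expect_equal(sum(c12$direction^2), 1, tolerance = 1e-12)

  expect_error(make_cylinder(c(0, 0, 0), c(1, 0, 0), radius = 0), "radius")
  expect_error(make_cylinder(c(0, 0, 0), c(0, 0, 0), radius = 5), "nonzero")
})

test_that("canal_volume handles the trivial occlusion cases", {
  cyl <- make_cylinder(c(0, 0, 0), c(1, 0, 0), length = 90, radius = 10)
  v_empty <- canal_volume(list(), cyl, 0.3)
  expect_equal(v_empty, cyl$volume, tolerance = 0.002)

  # cylinder fully embedded in a solid block
  occ <- array(TRUE, c(100, 24, 24))
  block <- mask_to_mesh(binary_mask(occ, spacing = c(1, 1, 1),
                                    origin = c(-5.5, -11.5, -11.5)))
  expect_lt(canal_volume(list(block), cyl, 0.3), 0.002 * cyl$volume)

  # half-space covering exactly half the length
  half <- array(TRUE, c(60, 40, 40))
  hblock <- mask_to_mesh(binary_mask(half, spacing = c(1, 1, 1),
                                     origin = c(45.5, -19.5, -19.5)))
  v_half <- canal_volume(list(hblock), cyl, 0.3)
  expect_equal(v_half, cyl$volume / 2, tolerance = 0.005)
  # finer-grid cross-check
  expect_equal(canal_volume(list(hblock), cyl, 0.15), v_half, tolerance = 0.005)

  expect_error(canal_volume(list(), cyl, 0), "resolution")
  open <- surface_mesh(hblock$vertices, hblock$faces[-1, ])
  expect_error(canal_volume(list(open), cyl, 0.3), "watertight")
})

test_that("canal_volume is monotone in added occluders", {
  cyl <- make_cylinder(c(-20, 0, 0), c(1, 0, 0), length = 40, radius = 8)
  b1 <- apply_transform(cube_mesh(side = 10, origin = c(-12, -5, -5)),
                        rigid_transform())
  b2 <- cube_mesh(side = 10, origin = c(2, -5, -14))
  v0 <- canal_volume(list(), cyl, 0.3)
  v1 <- canal_volume(list(b1), cyl, 0.3)
  v2 <- canal_volume(list(b1, b2), cyl, 0.3)
  expect_lte(v1, v0)
  expect_lte(v2, v1)
  expect_lt(v1, v0) # b1 genuinely intersects
})

test_that("delta-V bookkeeping and rigid invariance hold", {
  cyl <- make_cylinder(c(-20, 0, 0), c(1, 0, 0), length = 40, radius = 8)
  b_pre <- cube_mesh(side = 12, origin = c(-8, -6, 2))
  b_post <- apply_transform(b_pre, rigid_transform(translation = c(0, 0, 4)))
  res <- measure_delta_v(list(b_pre), list(b_post), cyl, 0.2)
  expect_identical(res$delta_v, res$v_post - res$v_pre)
  expect_gt(res$delta_v, 0) # lifting the block away frees volume
  ident <- measure_delta_v(list(b_pre), list(b_pre), cyl, 0.2)
  expect_identical(ident$delta_v, 0)

  # common rigid motion of cylinder and both segments leaves delta-V alone
  tr <- random_rigid(9)
  cyl_t <- make_cylinder(apply_transform(rbind(cyl$anchor), tr)[1, ],
                         as.numeric(tr$rotation %*% cyl$direction),
                         cyl$length, cyl$radius)
  res_t <- measure_delta_v(list(apply_transform(b_pre, tr)),
                           list(apply_transform(b_post, tr)), cyl_t, 0.2)
  expect_equal(res_t$delta_v, res$delta_v, tolerance = 0.005)
})

test_that("published per-segment rows are internally consistent", {
  t2 <- pcd_table2()
  expect_identical(nrow(t2), 16L)
  expect_equal(t2$delta_v_mm3, t2$v_post_mm3 - t2$v_pre_mm3, tolerance = 0.011)
  p01 <- t2[t2$patient == "P01", ]
  expect_equal(p01$v_post_mm3 - p01$v_pre_mm3, 3587.24)
  # the per-row CV column is SD over mean of the rater-averaged delta-V
  expect_equal(round(t2$sd_delta_v_mm3 / t2$delta_v_mm3, 2), t2$cv_delta_v)
  # every v_pre/v_post lies inside its cylinder volume
  vcyl <- pi * t2$cylinder_radius_mm^2 * t2$cylinder_height_mm
  expect_true(all(t2$v_pre_mm3 > 0 & t2$v_pre_mm3 < vcyl))
  expect_true(all(t2$v_post_mm3 > 0 & t2$v_post_mm3 < vcyl))
})
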