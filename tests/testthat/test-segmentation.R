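test_that("threshold_mask selects exactly the HU window and is monotone", {
  vol <- ct_volume(array(1000, c(5, 5, 5)))
  expect_true(all(threshold_mask(vol, 200, 2000)$occupancy))
  expect_false(any(threshold_mask(vol, 1500)$occupancy))
  expect_error(threshold_mask(vol, 10, 10), "lo < hi")

  set.seed(21)
  noisy <- ct_volume(array(rnorm(17^3, 300, 400), c(17, 17, 17)))
  narrow <- threshold_mask(noisy, 100, 500)
  wide <- threshold_mask(noisy, 0, 800)
  expect_true(all(wide$occupancy[narrow$occupancy])) # widening never removes
})

test_that("thresholding a binary phantom recovers the generative voxel count", {
  spec <- small_phantom_spec(seed = 3, supersample = 1, tilt = FALSE)
  ph <- generate_phantom(spec)
  mask <- threshold_mask(ph$pre, 200)
  # count voxel centers inside the analytic solids directly
  d <- dim(ph$pre$voxels)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  world <- canal3d:::grid_to_world(ph$pre, idx)
  solids <- c(ph$truth$solids_caudal, ph$truth$solids_cranial_pre)
  expect_identical(sum(mask$occupancy),
                   sum(canal3d:::points_in_solids(world, solids)))
})

test_that("fill_mask fills cavities, is idempotent, and never removes voxels", {
  solid <- binary_mask(array(TRUE, c(6, 6, 6)), spacing = c(1, 1, 1))
  expect_identical(fill_mask(solid, "per_slice")$occupancy, solid$occupancy)

  shell <- shell_mask(outer = 6, inner = 4, spacing = 0.7)
  filled <- fill_mask(shell, mode = "3d")
  expect_identical(filled$occupancy, oracle_fill_3d(shell$occupancy))
  expect_true(all(filled$occupancy[shell$occupancy]))
  expect_identical(fill_mask(filled, "3d")$occupancy, filled$occupancy)

  # open C-shaped region in one slice: connected to the outside, stays open
  occ <- array(FALSE, c(12, 12, 3))
  occ[3:9, 3:9, 2] <- TRUE
  occ[5:7, 5:12, 2] <- FALSE # channel to the border
  cmask <- binary_mask(occ, spacing = c(1, 1, 1))
  expect_identical(fill_mask(cmask, "per_slice")$occupancy, occ)
  expect_error(fill_mask(binary_mask(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("per-slice filling closes 2D cavities even when open in 3D", {
  # vertical tube: hollow in every axial slice but open at both z ends
  occ <- array(FALSE, c(10, 10, 5))
  occ[3:8, 3:8, ] <- TRUE
  occ[5:6, 5:6, ] <- FALSE
  tube <- binary_mask(occ, spacing = c(1, 1, 1))
  expect_true(all(fill_mask(tube, "per_slice")$occupancy[3:8, 3:8, ]))
  expect_identical(fill_mask(tube, "3d")$occupancy, occ) # open via z in 3D
})

test_that("largest_component matches the brute-force labelling oracle", {
  occ <- array(FALSE, c(12, 12, 12))
  occ[2:9, 2:9, 2:9] <- TRUE   # 512 voxels
  occ[11, 11, 11] <- TRUE      # lone voxel
  m <- binary_mask(occ, spacing = c(1, 1, 1))
  keep <- largest_component(m)
  expect_identical(sum(keep$occupancy), 512L)
  expect_identical(largest_component(keep)$occupancy, keep$occupancy)

  set.seed(22)
  rocc <- array(runif(10^3) < 0.2, c(10, 10, 10))
  if (any(rocc)) {
    lab <- oracle_label_26(rocc)
    sizes <- tabulate(lab[lab > 0])
    best <- order(-sizes, seq_along(sizes))[1]
    expect_identical(largest_component(binary_mask(rocc, spacing = c(1, 1, 1)))$occupancy,
                     array(lab == best, dim(rocc)))
  }
  expect_error(largest_component(binary_mask(array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("Dice similarity matches its definition and properties", {
  cube <- array(FALSE, c(30, 20, 20))
  cube[6:15, 6:15, 6:15] <- TRUE
  shifted <- array(FALSE, c(30, 20, 20))
  shifted[11:20, 6:15, 6:15] <- TRUE
  g <- list(spacing = c(1, 1, 1))
  m1 <- binary_mask(cube, spacing = g$spacing)
  m2 <- binary_mask(shifted, spacing = g$spacing)
  expect_identical(dice_similarity(m1, m1), 1)
  expect_equal(dice_similarity(m1, m2), 0.5) # overlap 500 of 1000+1000
  expect_identical(dice_similarity(m1, m2), dice_similarity(m2, m1))
  docc <- array(FALSE, dim(cube))
  docc[1, 1, 1] <- TRUE
  disjoint <- binary_mask(docc, spacing = g$spacing)
  expect_identical(dice_similarity(m1, disjoint), 0)

  set.seed(23)
  for (i in 1:5) {
    a <- binary_mask(array(runif(6^3) < 0.4, c(6, 6, 6)), spacing = c(1, 1, 1))
    b <- binary_mask(array(runif(6^3) < 0.4, c(6, 6, 6)), spacing = c(1, 1, 1))
    if (!any(a$occupancy) && !any(b$occupancy)) next
    d <- dice_similarity(a, b)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
  other_grid <- binary_mask(cube, spacing = c(2, 1, 1))
  expect_error(dice_similarity(m1, other_grid), "different grids")
  empty <- binary_mask(array(FALSE, dim(cube)), spacing = g$spacing)
  expect_error(dice_similarity(empty, empty), "both masks are empty")
})

test_that("resample_mask maps masks across grids by nearest neighbour", {
  m <- ball_mask(r = 4, spacing = 1)
  # same geometry expressed with a translated origin: resampling onto the
  # original grid recovers the original occupancy
  shifted <- binary_mask(m$occupancy, spacing = m$spacing, origin = c(10, 0, 0))
  target <- binary_mask(array(FALSE, dim(m$occupancy)), spacing = m$spacing,
                        origin = c(10, 0, 0))
  back <- resample_mask(shifted, target)
  expect_identical(back$occupancy, m$occupancy)
  expect_equal(dice_similarity(back, shifted), 1)
})

test_that("segmentation with noise still recovers the clean phantom masks", {
  clean <- generate_phantom(small_phantom_spec(seed = 5, noise_sd = 0))
  noisy <- generate_phantom(small_phantom_spec(seed = 5, noise_sd = 50))
  seg_clean <- segment_structure(clean$pre, lo = 226, hi = 1200)
  seg_noisy <- segment_structure(noisy$pre, lo = 226, hi = 1200)
  expect_gt(dice_similarity(seg_noisy$mask,
                            resample_mask(seg_clean$mask, seg_noisy$mask)), 0.99)
})
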