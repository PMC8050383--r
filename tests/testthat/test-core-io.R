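test_that("NIfTI volumes round-trip losslessly with geometry", {
  set.seed(11)
  vol <- ct_volume(array(round(rnorm(18 * 16 * 14, 100, 300)), c(18, 16, 14)),
                   spacing = c(0.6, 0.6, 0.6), origin = c(-5, 2, 7))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_volume(vol, f)
  back <- read_ct_volume(f)
  expect_identical(back$voxels, vol$voxels)
  # geometry fields pass through single-precision NIfTI header slots
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  expect_equal(back$orientation, vol$orientation, tolerance = 1e-6)
})

test_that("DICOM series round-trip, cross-format equality, and gap detection", {
  set.seed(12)
  vol <- ct_volume(array(round(rnorm(20 * 18 * 12, 200, 400)), c(20, 18, 12)),
                   spacing = c(0.6, 0.6, 0.6), origin = c(3, -4, 10))
  dd <- withr::local_tempdir()
  write_dicom_series(vol, dd)
  back <- read_ct_volume(dd, format = "dicom_series")
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)

  # same volume through NIfTI must agree with the DICOM read
  fn <- withr::local_tempfile(fileext = ".nii")
  write_ct_volume(vol, fn)
  via_nifti <- read_ct_volume(fn)
  expect_equal(via_nifti$voxels, back$voxels, tolerance = 1e-12)
  expect_equal(via_nifti$origin, back$origin, tolerance = 1e-9)

  # removing a slice must be reported with its index
  file.remove(file.path(dd, "slice_0005.dcm"))
  expect_error(read_ct_volume(dd, format = "dicom_series"),
               "missing slice at index 5")
})

test_that("an independent DICOM reader agrees with the writer", {
  vol <- ct_volume(array(seq_len(8 * 6 * 4) * 3 - 500, c(8, 6, 4)),
                   spacing = c(0.7, 0.8, 1.1), origin = c(-2, 1, 5))
  dd <- withr::local_tempdir()
  write_dicom_series(vol, dd)
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom,sys,json\n",
    "d = pydicom.dcmread(sys.argv[1])\n",
    "print(json.dumps({'rows': int(d.Rows), 'cols': int(d.Columns),",
    " 'px': int(d.pixel_array[2, 4]),",
    " 'ipp': [float(v) for v in d.ImagePositionPatient],",
    " 'spacing': [float(v) for v in d.PixelSpacing]}))")),
    file.path(dd, "slice_0003.dcm")), stdout = TRUE)
  info <- jsonlite::fromJSON(out)
  expect_identical(info$rows, 6L)
  expect_identical(info$cols, 8L)
  expect_identical(info$px, as.integer(vol$voxels[5, 3, 3]))
  expect_equal(info$ipp, vol$origin + c(0, 0, 2 * 1.1), tolerance = 1e-9)
  expect_equal(info$spacing, c(0.8, 0.7), tolerance = 1e-9)
})

test_that("mesh files round-trip across STL, PLY and OBJ", {
  cube <- cube_mesh(side = 2, origin = c(-1, -1, -1)) # float32-exact coords
  for (fmt in c("stl", "stl_ascii", "ply", "obj")) {
    f <- withr::local_tempfile(fileext = paste0(".", if (fmt == "stl_ascii") "stl" else fmt))
    write_mesh(cube, f, format = fmt)
    back <- read_mesh(f, format = fmt)
    expect_equal(mesh_volume(back), 8, tolerance = 1e-12)
    expect_equal(mesh_area(back), 24, tolerance = 1e-12)
    expect_true(is_watertight(back))
  }
  # PLY -> STL -> PLY keeps the enclosed volume
  m <- mask_to_mesh(ball_mask(r = 4, spacing = 1))
  p1 <- withr::local_tempfile(fileext = ".ply")
  p2 <- withr::local_tempfile(fileext = ".stl")
  p3 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, p1)
  write_mesh(read_mesh(p1), p2)
  write_mesh(read_mesh(p2), p3)
  expect_equal(mesh_volume(read_mesh(p3)), mesh_volume(m), tolerance = 1e-6)
  expect_error(read_mesh(withr::local_tempfile(fileext = ".stl")), "not found")
  empty <- withr::local_tempfile(fileext = ".ply")
  file.create(empty)
  expect_error(read_mesh(empty), "empty")
})

test_that("landmark sets preserve order and agree between CSV and JSON", {
  set.seed(13)
  lm <- landmark_set(matrix(rnorm(54, sd = 30), ncol = 3),
                     names = sprintf("L%02d", 1:18), frame = "preop")
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, fc)
  write_landmarks(lm, fj)
  a <- read_landmarks(fc, expected_count = 18)
  b <- read_landmarks(fj, expected_count = 18)
  expect_identical(rownames(a$points), rownames(lm$points))
  expect_equal(a$points, b$points, tolerance = 1e-12)
  expect_equal(unname(a$points), unname(lm$points), tolerance = 1e-12)
  # count and duplicate-name violations
  expect_error(read_landmarks(fc, expected_count = 17), "expected 17")
  dup <- data.frame(name = c("a", "a", "b"), x = 1:3, y = 1:3, z = 1:3)
  fd <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, fd, row.names = FALSE)
  expect_error(read_landmarks(fd), "duplicate")
})

test_that("mask volume is invariant under grid translation", {
  occ <- ball_mask(r = 3, spacing = 0.5)
  moved <- binary_mask(occ$occupancy, spacing = occ$spacing, origin = c(100, -50, 3))
  expect_identical(mask_volume(occ), mask_volume(moved))
})
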