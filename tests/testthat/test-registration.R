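test_that("rigid landmark fit recovers known transforms exactly", {
  set.seed(41)
  P <- matrix(rnorm(18 * 3, sd = 25), ncol = 3)
  fixed <- landmark_set(P, frame = "postop")
  ident <- fit_rigid_landmarks(fixed, fixed)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(ident, "rms"), 1e-12)

  tr0 <- rigid_transform(canal3d:::rotation_about_axis(c(0, 0, 1), pi / 6),
                         c(5, -3, 2))
  moving <- landmark_set(apply_transform(P, invert_transform(tr0)),
                         rownames(P), "preop")
  fit <- fit_rigid_landmarks(moving, fixed)
  expect_equal(fit$rotation, tr0$rotation, tolerance = 1e-9)
  expect_equal(fit$translation, tr0$translation, tolerance = 1e-9)
  expect_lt(attr(fit, "rms"), 1e-9)

  # degenerate inputs
  expect_error(fit_rigid_landmarks(landmark_set(P[1:2, ]), landmark_set(P[1:2, ])),
               "at least 3")
  line <- landmark_set(cbind(1:5, 2 * (1:5), 3 * (1:5)))
  expect_error(fit_rigid_landmarks(line, line), "collinear")
  renamed <- landmark_set(P, names = rev(sprintf("P%02d", 1:18)))
  expect_error(fit_rigid_landmarks(renamed, fixed), "names/order")
})

test_that("noisy landmarks give calibrated residuals and proper rotations", {
  n <- 18
  sigma <- 0.5
  tr0 <- rigid_transform(canal3d:::rotation_about_axis(c(1, 2, 0.5), 0.4),
                         c(4, -7, 3))
  angles <- trans <- rmss <- numeric(100)
  set.seed(42)
  base <- matrix(rnorm(n * 3, sd = 25), ncol = 3)
  for (i in 1:100) {
    fx <- base + matrix(rnorm(n * 3, 0, sigma), ncol = 3)
    mv <- apply_transform(base, invert_transform(tr0)) +
      matrix(rnorm(n * 3, 0, sigma), ncol = 3)
    fit <- fit_rigid_landmarks(landmark_set(mv), landmark_set(fx))
    dR <- fit$rotation %*% t(tr0$rotation)
    angles[i] <- acos(min(1, (sum(diag(dR)) - 1) / 2)) * 180 / pi
    trans[i] <- sqrt(sum((fit$translation - tr0$translation)^2))
    rmss[i] <- attr(fit, "rms")
    expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  expect_lt(mean(angles), 1)
  expect_lt(mean(trans), 0.5)
  # residual RMS calibration for noise on both sets: per-coordinate RMS is
  # sigma * sqrt(2 (1 - 3/n)); the per-point (Euclidean) RMS reported by the
  # fit is sqrt(3) times that
  expect_equal(mean(rmss), sqrt(3) * sigma * sqrt(2 * (1 - 3 / n)),
               tolerance = 0.3)
})

test_that("apply_transform is rigid: volumes invariant, exactly invertible", {
  cube <- cube_mesh()
  expect_identical(apply_transform(cube, rigid_transform())$vertices, cube$vertices)
  tr <- random_rigid(7)
  moved <- apply_transform(cube, tr)
  expect_equal(mesh_volume(moved), 1, tolerance = 1e-12)
  back <- apply_transform(moved, invert_transform(tr))
  expect_equal(back$vertices, cube$vertices, tolerance = 1e-9)
  comp <- compose_transforms(invert_transform(tr), tr)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-12)
})

test_that("Hausdorff distance equals the brute-force vertex oracle", {
  ball <- mask_to_mesh(ball_mask(r = 5, spacing = 1))
  expect_identical(hausdorff_distance(ball, ball)$max, 0)

  cube <- cube_mesh(side = 10)
  moved <- apply_transform(cube, rigid_transform(translation = c(1, 0, 0)))
  expect_equal(hausdorff_distance(cube, moved)$max, 1, tolerance = 1e-12)

  set.seed(43)
  A <- surface_mesh(matrix(rnorm(500 * 3, sd = 5), ncol = 3), matrix(c(1, 2, 3), 1))
  B <- surface_mesh(matrix(rnorm(400 * 3, sd = 5), ncol = 3), matrix(c(1, 2, 3), 1))
  hd <- hausdorff_distance(A, B, mode = "symmetric")
  expect_identical(hd$per_vertex, oracle_nn(A$vertices, B$vertices))
  expect_identical(hd$per_vertex_ba, oracle_nn(B$vertices, A$vertices))
  expect_identical(hd$max, max(max(hd$per_vertex), max(hd$per_vertex_ba)))
  expect_gte(hd$max, max(hd$per_vertex))

  # symmetric mode is a metric: triangle inequality on random triples
  for (i in 1:5) {
    pts <- lapply(1:3, function(j) {
      surface_mesh(matrix(rnorm(60, sd = 3), ncol = 3), matrix(c(1, 2, 3), 1))
    })
    h <- function(a, b) hausdorff_distance(a, b, mode = "symmetric")$max
    expect_lte(h(pts[[1]], pts[[3]]), h(pts[[1]], pts[[2]]) + h(pts[[2]], pts[[3]]) + 1e-12)
  }
  empty <- surface_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3))
  expect_error(hausdorff_distance(empty, cube), "empty")
})

test_that("distance CDFs are monotone, end at 1, and count correctly", {
  cdf0 <- distance_cdf(rep(0, 10))
  expect_identical(cdf0$distance, 0)
  expect_identical(cdf0$cumulative_fraction, 1)

  cdf <- distance_cdf(c(1, 2, 3, 4))
  expect_equal(cdf$cumulative_fraction[cdf$distance == 2], 0.5)
  expect_true(all(diff(cdf$cumulative_fraction) >= 0))
  expect_identical(tail(cdf$cumulative_fraction, 1), 1)

  set.seed(44)
  d <- abs(rnorm(200, 0.8, 0.5))
  cdf2 <- distance_cdf(d)
  expect_equal(max(cdf2$cumulative_fraction[cdf2$distance <= 1]), mean(d <= 1))
  expect_error(distance_cdf(numeric(0)), "no distances")
})
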