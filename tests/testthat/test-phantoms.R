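test_that("the symmetric phantom is exactly mirror-symmetric by construction", {
  ph <- tiny_phantom()
  expect_equal(symmetry_ratio(ph$grid, ph$truth_plane), 1)

  # index-flip of the occupancy equals itself
  d <- dim(ph$grid$occupancy)
  expect_identical(ph$grid$occupancy[d[1]:1, , ], ph$grid$occupancy)

  # off-plane voxels pair up: with the plane between voxel columns every
  # foreground voxel is off-plane, so the total count is even
  expect_equal(ph$grid$n_foreground %% 2L, 0L)

  # landmarks: CG and ANS on the midplane, orbitale mirror-symmetric
  expect_equal(ph$landmarks$CG[1], 0)
  expect_equal(ph$landmarks$ANS[1], 0)
  expect_equal(ph$landmarks$OrR * c(-1, 1, 1), ph$landmarks$OrL)

  expect_error(phantom_spec(spacing = 4), "too coarse")
  expect_error(phantom_spec(semi_axes = c(5, 26, 24), shell_mm = 3),
               "twice the shell")
})

test_that("protrusions grow like a spherical shell and break symmetry monotonically", {
  ph <- tiny_phantom()
  expect_identical(add_protrusion(ph, "left", 0), ph)
  expect_error(add_protrusion(ph, "left", 0.5, thickness_mm = 1), "exceed")

  # voxelized shell volume approximates 4 pi r^2 t at 1 mm resolution
  ph1 <- make_symmetric_phantom(phantom_spec(spacing = 1))
  suppressWarnings(p30 <- add_protrusion(ph1, "left", 30))
  added <- p30$grid$n_foreground - ph1$grid$n_foreground
  expect_lt(abs(added / (4 * pi * 30^2 * 1) - 1), 0.1)

  # SR at the truth plane strictly decreases with protrusion radius
  radii <- c(5, 10, 20, 30, 40, 50)
  srs <- vapply(radii, function(r) {
    suppressWarnings(pr <- add_protrusion(ph, "left", r))
    symmetry_ratio(pr$grid, pr$truth_plane)
  }, numeric(1))
  expect_true(all(diff(srs) < 0))
  expect_true(all(srs < 1))

  # the right-side attachment mirrors the left one
  suppressWarnings(pl <- add_protrusion(ph, "left", 10))
  suppressWarnings(pr <- add_protrusion(ph, "right", 10))
  expect_equal(pl$grid$n_foreground, pr$grid$n_foreground)
})

test_that("rigid poses resample faithfully and transform the truth analytically", {
  ph <- tiny_phantom()
  expect_identical(apply_rigid(ph)$grid$occupancy, ph$grid$occupancy)
  expect_equal(apply_rigid(ph)$grid$origin, ph$grid$origin)

  # 90 degrees about z is an exact permutation (isotropic spacing)
  r90 <- apply_rigid(ph, c(0, 0, 90))
  expect_equal(r90$grid$n_foreground, ph$grid$n_foreground)
  expect_equal(symmetry_ratio(r90$grid, r90$truth_plane), 1)

  # small rotations lose under 2% of the foreground to resampling
  r10 <- apply_rigid(ph, c(0, 10, 0), translation = c(2, -1, 3))
  expect_lt(abs(r10$grid$n_foreground / ph$grid$n_foreground - 1), 0.02)
  expect_equal(plane_angle(r10$truth_plane, ph$truth_plane), 10,
               tolerance = 1e-6)

  # landmarks ride along: the landmark plane still matches the truth plane
  expect_lt(plane_angle(landmark_plane(r10$landmarks), r10$truth_plane), 1e-6)
})

test_that("unilateral scaling breaks symmetry; landmark jitter is reproducible", {
  ph <- tiny_phantom()
  expect_identical(add_asymmetry(ph, "unilateral_scale", 1), ph)
  expect_error(add_asymmetry(ph, "unilateral_scale", 1.6), "0.5, 1.5")

  sc <- add_asymmetry(ph, "unilateral_scale", 1.3)
  expect_lt(symmetry_ratio(sc$grid, sc$truth_plane), 1)
  expect_gt(sc$grid$n_foreground, 0.8 * ph$grid$n_foreground)

  j1 <- add_asymmetry(ph, "landmark_jitter", 2, seed = 7)
  j2 <- add_asymmetry(ph, "landmark_jitter", 2, seed = 7)
  expect_identical(j1$landmarks, j2$landmarks)
  expect_false(identical(j1$landmarks$CG, ph$landmarks$CG))
  expect_identical(j1$grid$occupancy, ph$grid$occupancy)
})
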