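test_that("paired_count handles the constructed trivial cases", {
  # two voxels mirror-symmetric about the plane between them
  occ <- array(0L, c(2, 1, 1)); occ[] <- 1L
  g <- voxel_grid(occ)
  pl <- plane_from_normal(c(1, 0, 0), point = c(1, 0.5, 0.5))
  expect_equal(paired_count(g, pl), list(paired = 2L, total = 2L))
  expect_equal(symmetry_ratio(g, pl), 1)

  # reflection landing outside the grid is unpaired
  occ1 <- array(0L, c(2, 1, 1)); occ1[1, 1, 1] <- 1L
  g1 <- voxel_grid(occ1)
  far <- plane_from_normal(c(1, 0, 0), point = c(10, 0, 0))
  expect_equal(paired_count(g1, far), list(paired = 0L, total = 1L))
  expect_equal(symmetry_ratio(g1, far), 0)

  expect_error(paired_count(voxel_grid(array(0L, c(2, 2, 2))), far),
               "no foreground")
})

test_that("paired_count agrees exactly with the brute-force oracle", {
  set.seed(31)
  for (rep in 1:60) {
    g <- random_grid(c(8, 8, 8), p = runif(1, 0.1, 0.5))
    pl <- random_plane(anchor = c(4, 4, 4))
    expect_identical(paired_count(g, pl)$paired, oracle_paired_count(g, pl)$paired)
  }
  # anisotropic spacing and shifted origins
  for (rep in 1:40) {
    g <- random_grid(c(6, 7, 5), p = 0.3, spacing = runif(3, 0.5, 2.5),
                     origin = rnorm(3, 0, 5))
    pl <- random_plane(anchor = grid_centroid(g), d_sd = 4)
    expect_identical(paired_count(g, pl)$paired, oracle_paired_count(g, pl)$paired)
  }
})

test_that("SR is bounded, perfect on symmetric phantoms and invariant under exact grid motions", {
  ph <- tiny_phantom()
  expect_equal(symmetry_ratio(ph$grid, ph$truth_plane), 1)

  set.seed(32)
  srs <- replicate(25, symmetry_ratio(ph$grid, random_plane(anchor = grid_centroid(ph$grid), d_sd = 10)))
  expect_true(all(srs >= 0 & srs <= 1))

  # joint integer-voxel translation of grid and plane leaves SR unchanged
  pl <- random_plane(anchor = grid_centroid(ph$grid), d_sd = 5)
  shift <- c(3, -2, 5) * ph$grid$spacing
  g2 <- voxel_grid(ph$grid$occupancy, ph$grid$spacing, ph$grid$origin + shift)
  pl2 <- sym_plane(pl$phi, pl$theta, pl$d, pl$anchor + shift)
  expect_identical(paired_count(ph$grid, pl)$paired, paired_count(g2, pl2)$paired)

  # joint 90-degree rotation about z (array permutation) leaves SR unchanged
  d <- dim(ph$grid$occupancy)
  occ_rot <- aperm(ph$grid$occupancy, c(2, 1, 3))[d[2]:1, , ]
  g_rot <- voxel_grid(occ_rot, ph$grid$spacing[c(2, 1, 3)], c(0, 0, 0))
  # voxel (i,j,k) -> (d2+1-j, i, k); physical map relative to origins
  rot_pt <- function(p) cbind(d[2] * ph$grid$spacing[2] - p[, 2] + 0, p[, 1], p[, 3])
  base <- ph$grid$origin
  pl_rot <- plane_from_normal(
    c(-pl$normal[2], pl$normal[1], pl$normal[3]),
    point = drop(rot_pt(t(pl$anchor - base) )) - pl$d * c(-pl$normal[2], pl$normal[1], pl$normal[3]),
    anchor = drop(rot_pt(t(pl$anchor - base))))
  expect_identical(paired_count(ph$grid, pl)$paired, paired_count(g_rot, pl_rot)$paired)
})

test_that("initial plane is the bounding-box median plane and translates with it", {
  occ <- array(0L, c(40, 4, 4))
  occ[11:30, 2:3, 2:3] <- 1L  # foreground spanning x in [10, 30] mm
  g <- voxel_grid(occ)
  pl <- initial_plane(g)
  expect_equal(pl$normal, c(1, 0, 0))
  expect_lt(abs(signed_distance(c(20, 2, 2), pl)), 1e-9)  # passes x = 20

  g2 <- voxel_grid(occ, origin = c(5, 0, 0))
  expect_lt(abs(signed_distance(c(25, 2, 2), initial_plane(g2))), 1e-9)

  ph <- tiny_phantom()
  expect_equal(plane_angle(initial_plane(ph$grid), ph$truth_plane), 0)
  expect_lt(abs(initial_plane(ph$grid)$d - ph$truth_plane$d), 1e-9)
})

test_that("find_osp recovers a planted optimum and is deterministic", {
  ph <- tiny_phantom()
  res <- find_osp(ph$grid)
  expect_s3_class(res, "osp_result")
  expect_equal(res$osr, 1)
  expect_lt(plane_angle(res$plane, ph$truth_plane), 0.1)
  expect_equal(res$osr, res$paired / res$total)

  res2 <- find_osp(ph$grid)
  expect_identical(res$plane$phi, res2$plane$phi)
  expect_identical(res$plane$theta, res2$plane$theta)
  expect_identical(res$plane$d, res2$plane$d)
  expect_identical(res$osr, res2$osr)

  # the trace records stage-1 scan plus refinement evaluations
  expect_true(all(c("phi", "theta", "d", "paired", "stage", "sr") %in%
                    names(res$search_trace)))
  expect_equal(nrow(res$search_trace), res$n_evaluations)
  expect_error(find_osp(ph$grid, coarse_deg = -1), "positive")
})

test_that("find_osp beats an exhaustive coarse evaluation grid and the planted plane", {
  ph <- tiny_phantom()
  res <- find_osp(ph$grid, keep_trace = FALSE)
  # independent exhaustive oracle at 5 degrees / 2 mm
  anchor <- grid_centroid(ph$grid)
  best_oracle <- 0
  for (phi in seq(0, pi, by = 5 * pi / 180))
    for (theta in seq(0, pi, by = 5 * pi / 180))
      for (d in seq(-20, 20, by = 2)) {
        sr <- symmetry_ratio(ph$grid, sym_plane(phi, theta, d, anchor))
        if (sr > best_oracle) best_oracle <- sr
      }
  expect_gte(res$osr, best_oracle)
  expect_gte(res$osr, symmetry_ratio(ph$grid, ph$truth_plane))
})

test_that("find_osp recovers a rotated planted plane within a degree", {
  ph <- tiny_phantom()
  rot <- apply_rigid(ph, c(0, 0, 10))
  res <- find_osp(rot$grid, keep_trace = FALSE)
  expect_lt(plane_angle(res$plane, rot$truth_plane), 1)
})
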