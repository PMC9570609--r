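test_that("split_by_plane matches the per-voxel sign oracle", {
  set.seed(51)
  g <- random_grid(c(7, 6, 5), p = 0.4, spacing = c(1.2, 0.9, 1.5),
                   origin = c(-2, 1, 0))
  pl <- random_plane(anchor = grid_centroid(g), d_sd = 2)
  parts <- split_by_plane(g, pl)
  idx <- which(g$occupancy == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    ctr <- g$origin + (idx[r, ] - 0.5) * g$spacing
    s <- sum(pl$normal * (ctr - pl$anchor)) + pl$d
    side <- if (s >= 0) parts$A else parts$B
    other <- if (s >= 0) parts$B else parts$A
    expect_equal(side$occupancy[idx[r, 1], idx[r, 2], idx[r, 3]], 1L)
    expect_equal(other$occupancy[idx[r, 1], idx[r, 2], idx[r, 3]], 0L)
  }
  expect_equal(parts$A$n_foreground + parts$B$n_foreground, g$n_foreground)

  # symmetric phantom split by the truth plane is balanced
  ph <- tiny_phantom()
  sp <- split_by_plane(ph$grid, ph$truth_plane)
  expect_equal(sp$A$n_foreground, sp$B$n_foreground)

  # plane outside the object leaves one side empty
  off <- plane_from_normal(c(1, 0, 0), point = c(1e4, 0, 0))
  sp2 <- split_by_plane(ph$grid, off)
  expect_equal(sp2$A$n_foreground * sp2$B$n_foreground, 0L)
})

test_that("hausdorff is symmetric, zero on identical sets, and matches the double loop", {
  A <- matrix(rnorm(60), ncol = 3)
  expect_equal(hausdorff(A, A), 0)
  expect_equal(hausdorff(c(0, 0, 0), c(3, 4, 0)), 5)

  set.seed(52)
  B <- matrix(rnorm(600, 2, 3), ncol = 3)
  A2 <- matrix(rnorm(600, 0, 3), ncol = 3)
  dm <- as.matrix(stats::dist(rbind(A2, B)))[seq_len(nrow(A2)),
                                             nrow(A2) + seq_len(nrow(B))]
  oracle <- max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
  expect_equal(hausdorff(A2, B), oracle)
  expect_equal(hausdorff(B, A2), oracle)
  expect_error(hausdorff(A2, matrix(numeric(0), 0, 3)), "nonempty")
})

test_that("jaccard and dice obey their algebraic identities", {
  base <- array(0L, c(6, 2, 2))
  a <- base; a[1:4, 1, 1] <- 1L            # |A| = 4
  b <- base; b[3:6, 1, 1] <- 1L            # |B| = 4, |A&B| = 2
  ga <- voxel_grid(a); gb <- voxel_grid(b)
  expect_equal(jaccard(ga, ga), 1)
  expect_equal(dice(ga, ga), 1)
  expect_equal(jaccard(ga, gb), 1 / 3)     # half-overlap construction
  expect_equal(dice(ga, gb), 1 / 2)
  disj <- base; disj[5:6, 2, 2] <- 1L
  expect_equal(jaccard(ga, voxel_grid(disj)), 0)

  set.seed(53)
  for (rep in 1:20) {
    g1 <- random_grid(c(5, 5, 5), p = runif(1, 0.1, 0.6))
    g2 <- random_grid(c(5, 5, 5), p = runif(1, 0.1, 0.6))
    j <- jaccard(g1, g2); dcoef <- dice(g1, g2)
    expect_lt(abs(dcoef - 2 * j / (1 + j)), 1e-9)
    expect_true(j <= dcoef && dcoef <= 1 && j >= 0)
  }
  expect_error(jaccard(ga, voxel_grid(a, spacing = 2)), "share")
  expect_error(jaccard(voxel_grid(base), voxel_grid(base)), "empty")
})

test_that("assess_plane is exact on the symmetric phantom and consistent with direct overlap", {
  ph <- tiny_phantom()
  rep0 <- assess_plane(ph$grid, ph$truth_plane, method_label = "truth")
  vox_diag <- sqrt(sum(ph$grid$spacing^2))
  expect_lte(rep0$hd_mm, vox_diag)
  expect_gte(rep0$jsc, 0.98)
  expect_gte(rep0$dsc, 0.98)

  # oracle pipeline: explicit reflected grids give identical JSC/DSC
  pl <- random_plane(anchor = grid_centroid(ph$grid), d_sd = 2)
  parts <- split_by_plane(ph$grid, pl)
  if (parts$A$n_foreground > 0 && parts$B$n_foreground > 0) {
    refl <- reflect_points(voxel_centers(parts$B), pl)
    refB <- symplane:::bin_points_to_grid(refl, parts$A)
    repx <- assess_plane(ph$grid, pl)
    expect_equal(repx$jsc, jaccard(parts$A, refB))
    expect_equal(repx$dsc, dice(parts$A, refB))
    expect_lt(abs(repx$dsc - 2 * repx$jsc / (1 + repx$jsc)), 1e-9)
  }

  # a planted 20 mm unilateral protrusion pushes HD at least that far: the
  # sphere pole sticks radius-mm out from the jaw flank, beyond anything the
  # mirrored contralateral side can offer (study-scale phantom so the sphere
  # is small relative to the skull)
  big <- default_phantom()
  suppressWarnings(prot <- add_protrusion(big, "left", 20))
  rep20 <- assess_plane(prot$grid, prot$truth_plane)
  expect_gte(rep20$hd_mm, 20 - 2 * max(prot$grid$spacing))

  expect_error(assess_plane(ph$grid,
                            plane_from_normal(c(1, 0, 0), point = c(500, 0, 0))),
               "does not bisect")
})

test_that("assessments are invariant when the whole configuration is mirrored", {
  ph <- tiny_phantom()
  pl <- sym_plane(pi / 2, 0.2, 1.5, grid_centroid(ph$grid))
  rep1 <- assess_plane(ph$grid, pl)
  # mirror grid and plane across the x midplane of the grid (index flip)
  d <- dim(ph$grid$occupancy)
  g2 <- voxel_grid(ph$grid$occupancy[d[1]:1, , ], ph$grid$spacing, ph$grid$origin)
  mx <- ph$grid$origin[1] + d[1] * ph$grid$spacing[1] / 2
  n2 <- c(-pl$normal[1], pl$normal[2], pl$normal[3])
  pt <- pl$anchor - pl$d * pl$normal
  pt2 <- c(2 * mx - pt[1], pt[2], pt[3])
  a2 <- c(2 * mx - pl$anchor[1], pl$anchor[2], pl$anchor[3])
  rep2 <- assess_plane(g2, plane_from_normal(n2, point = pt2, anchor = a2))
  expect_equal(rep2$hd_mm, rep1$hd_mm, tolerance = 1e-9)
  expect_equal(rep2$jsc, rep1$jsc, tolerance = 0.02)
  expect_equal(rep2$dsc, rep1$dsc, tolerance = 0.02)
})

test_that("plane angle difference behaves on the degenerate cases", {
  p1 <- sym_plane(pi / 2, 0, 0)
  expect_equal(plane_angle(p1, p1), 0)
  expect_equal(plane_angle(p1, sym_plane(pi / 2, pi / 2, 0)), 90)
  anti <- plane_from_normal(c(-1, 0, 0), point = c(0, 0, 0))
  expect_equal(plane_angle(p1, anti), 0)
})

test_that("SR ranks planes like DSC across a plane sweep", {
  ph <- tiny_phantom()
  anchor <- grid_centroid(ph$grid)
  set.seed(54)
  angles <- seq(0, 12, length.out = 25) * pi / 180
  planes <- c(
    lapply(angles, function(a) plane_from_normal(
      c(cos(a), sin(a), 0), point = anchor, anchor = anchor)),
    lapply(seq(0, 6, length.out = 25), function(dd)
      sym_plane(pi / 2, 0, dd, anchor)))
  sr <- vapply(planes, function(p) symmetry_ratio(ph$grid, p), numeric(1))
  dsc <- vapply(planes, function(p) assess_plane(ph$grid, p)$dsc, numeric(1))
  expect_gt(stats::cor(sr, dsc, method = "spearman"), 0.9)
})

test_that("the wilcoxon comparison emits all pairs and exact p-values", {
  set.seed(55)
  n <- 20
  base <- data.frame(case = rep(1:n, 3),
                     method = rep(c("LSP", "SSP", "OSP"), each = n))
  base$hd_mm <- runif(3 * n, 5, 30)
  base$jsc <- runif(3 * n, 0, 1)
  base$dsc <- 2 * base$jsc / (1 + base$jsc)
  tab <- compare_methods_wilcoxon(base)
  expect_equal(nrow(tab), 9)  # 3 pairs x 3 assessments
  expect_setequal(unique(tab$comparison),
                  c("LSP vs SSP", "LSP vs OSP", "SSP vs OSP"))

  # identical paired samples: p = 1
  same <- base; same$hd_mm <- rep(runif(n), 3); same$jsc <- 0.5; same$dsc <- 2/3
  expect_true(all(compare_methods_wilcoxon(same)$p_value == 1))

  # one method uniformly better by a constant: smallest attainable p at n=20
  two <- base[base$method != "OSP", ]
  two$hd_mm[two$method == "SSP"] <- two$hd_mm[two$method == "LSP"] + 3
  tab2 <- compare_methods_wilcoxon(two)
  expect_equal(tab2$p_value[tab2$assessment == "hd_mm"], 2 * (1 / 2)^20)

  # exact path agrees with wilcox.test when there are no ties
  x <- c(12.1, 9.4, 15.2, 8.8, 11.0, 14.3, 10.5, 9.9)
  y <- c(10.0, 9.8, 13.0, 9.5, 10.2, 12.0, 11.1, 9.0)
  expect_equal(symplane:::signed_rank_exact_p(x, y),
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)

  expect_error(compare_methods_wilcoxon(base[-1, ]), "identical set of cases")
  expect_error(compare_methods_wilcoxon(base[base$case <= 4, ]), "at least 6")
})
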