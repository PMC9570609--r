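#' Specification of a synthetic skull phantom
#'
#' Stylized skull-like binary volume: a hollow ellipsoid shell (the cranial
#' vault) with optional symmetric orbit voids and a solid jaw block, built
#' exactly mirror-symmetric about its x-midplane. The phantom is geometric,
#' not anatomically faithful — the symmetry algorithms consume only binary
#' occupancy, so a known ground-truth plane is what matters for testing.
#'
#' @param semi_axes Outer ellipsoid semi-axes `(a, b, c)` in mm
#'   (x = left-right, y = back-front, z = inferior-superior); default
#'   `c(40, 52, 48)`, a slightly scaled-down adult cranium.
#' @param shell_mm Shell wall thickness in mm (default 3).
#' @param orbits Carve two symmetric spherical orbit voids (default `TRUE`).
#' @param jaw Add a solid ellipsoidal jaw block below the front of the shell
#'   (default `TRUE`); protrusions attach to its side.
#' @param spacing Voxel spacing in mm, scalar or length 3 (default 1.5).
#' @param margin_mm Empty margin around the geometry (default 6).
#' @param seed Integer seed used by randomized perturbations (default 1).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(40, 52, 48), shell_mm = 3,
                         orbits = TRUE, jaw = TRUE, spacing = 1.5,
                         margin_mm = 6, seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0), shell_mm > 0,
            length(spacing) == 3L, all(spacing > 0), margin_mm >= 0)
  if (!all(semi_axes > 2 * shell_mm))
    stop("semi-axes must exceed twice the shell thickness")
  if (shell_mm < max(spacing))
    stop("spacing too coarse to resolve the shell (thickness < spacing)")
  structure(list(semi_axes = as.numeric(semi_axes), shell_mm = shell_mm,
                 orbits = isTRUE(orbits), jaw = isTRUE(jaw),
                 spacing = as.numeric(spacing), margin_mm = margin_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Derived feature geometry, all in phantom coordinates (ellipsoid center at
# the origin, mid-sagittal plane x = 0). The vault is egg-shaped — flatter at
# the back (y < 0) and the base (z < 0) — so that, like a real cranium, the
# only mirror symmetry is the sagittal one; front-back and top-bottom mirror
# planes score clearly worse.
phantom_geometry <- function(spec) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; c <- spec$semi_axes[3]
  list(
    back_scale = 0.82,   # posterior semi-axis = 0.82 b
    base_scale = 0.85,   # inferior semi-axis = 0.85 c
    orbit_r = 0.22 * c,
    orbit_ctr = c(0.45 * a, 0.80 * b, 0.25 * c),   # +x orbit; mirrored at -x
    jaw_semi = c(0.30 * a, 0.25 * b, 0.22 * c),
    jaw_ctr = c(0, 0.60 * b, -0.85 * c))
}

#' Generate an exactly mirror-symmetric skull phantom
#'
#' Builds the occupancy for one half-grid from the implicit geometry and
#' mirrors it into the other half by an index flip, so the phantom is exactly
#' symmetric about the plane `x = 0` by construction: on a grid with an even
#' voxel count across x, `symmetry_ratio(grid, truth_plane)` is exactly 1.
#' Synthetic landmarks (CG and ANS on the midplane, OrR/OrL mirror-symmetric
#' at the orbit floors) are placed for the landmark-based baseline.
#'
#' @param spec A [phantom_spec].
#' @return An object of class `phantom`: `grid` ([voxel_grid]),
#'   `truth_plane` ([sym_plane] `x = 0`), `landmarks` ([landmark_set]) and
#'   the `spec` echo.
#' @export
make_symmetric_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; cc <- spec$semi_axes[3]
  sp <- spec$spacing
  g <- phantom_geometry(spec)
  m <- spec$margin_mm

  zlo <- if (spec$jaw) g$jaw_ctr[3] - g$jaw_semi[3] - m else -cc - m
  half_nx <- ceiling((a + m) / sp[1])
  nx <- 2L * half_nx
  origin_x <- -half_nx * sp[1]
  ylo <- -b - m; yhi <- b + m
  zhi <- cc + m
  ny <- ceiling((yhi - ylo) / sp[2])
  nz <- ceiling((zhi - zlo) / sp[3])

  # voxel centers of the +x half-grid
  xs <- origin_x + (seq_len(nx) - 0.5) * sp[1]
  ys <- ylo + (seq_len(ny) - 0.5) * sp[2]
  zs <- zlo + (seq_len(nz) - 0.5) * sp[3]
  xr <- xs[(half_nx + 1L):nx]

  X <- array(rep(xr, times = ny * nz), c(half_nx, ny, nz))
  Y <- array(rep(rep(ys, each = half_nx), times = nz), c(half_nx, ny, nz))
  Z <- array(rep(zs, each = half_nx * ny), c(half_nx, ny, nz))

  ell <- function(x, y, z, sa) (x / sa[1])^2 + (y / sa[2])^2 + (z / sa[3])^2
  # egg-shaped vault: posterior and inferior semi-axes are shrunk, so no
  # front-back or top-bottom mirror symmetry survives
  egg <- function(x, y, z, shrink) {
    sb <- ifelse(y >= 0, b, g$back_scale * b) - shrink
    sc <- ifelse(z >= 0, cc, g$base_scale * cc) - shrink
    (x / (a - shrink))^2 + (y / sb)^2 + (z / sc)^2
  }
  outer_e <- egg(X, Y, Z, 0)
  inner_e <- egg(X, Y, Z, spec$shell_mm)
  occ_half <- outer_e <= 1 & inner_e > 1
  if (spec$orbits) {
    oc <- g$orbit_ctr
    occ_half <- occ_half &
      ((X - oc[1])^2 + (Y - oc[2])^2 + (Z - oc[3])^2 > g$orbit_r^2)
  }
  if (spec$jaw) {
    occ_half <- occ_half |
      (ell(X - g$jaw_ctr[1], Y - g$jaw_ctr[2], Z - g$jaw_ctr[3], g$jaw_semi) <= 1)
  }

  occ <- array(0L, c(nx, ny, nz))
  occ[(half_nx + 1L):nx, , ] <- occ_half + 0L
  occ[half_nx:1L, , ] <- occ[(half_nx + 1L):nx, , ]  # mirror by index flip

  grid <- voxel_grid(occ, sp, origin = c(origin_x, ylo, zlo))
  truth <- plane_from_normal(c(1, 0, 0), point = c(0, 0, 0),
                             anchor = c(0, 0, 0))
  lm <- landmark_set(
    CG = c(0, 0.30 * b, 0.90 * cc),
    ANS = c(0, 0.95 * b, -0.10 * cc),
    OrR = c(-g$orbit_ctr[1], g$orbit_ctr[2], g$orbit_ctr[3] - g$orbit_r),
    OrL = c(g$orbit_ctr[1], g$orbit_ctr[2], g$orbit_ctr[3] - g$orbit_r))
  structure(list(grid = grid, truth_plane = truth, landmarks = lm,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("skull phantom\n")
  print(x$grid)
  print(x$truth_plane)
  invisible(x)
}

# Fixed protrusion attachment point on the jaw flank (phantom coordinates);
# side "left" is +x, "right" is -x.
protrusion_attachment <- function(spec, side = c("left", "right")) {
  side <- match.arg(side)
  g <- phantom_geometry(spec)
  p <- c(g$jaw_semi[1], g$jaw_ctr[2], g$jaw_ctr[3])
  if (side == "right") p[1] <- -p[1]
  p
}

# Grow a grid with zero padding (in voxels) per axis; lo/hi are length-3.
pad_grid <- function(grid, lo, hi) {
  d <- dim(grid$occupancy)
  occ <- array(0L, d + lo + hi)
  occ[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
    grid$occupancy
  voxel_grid(occ, grid$spacing, grid$origin - lo * grid$spacing)
}

#' Add a spherical-shell protrusion to a phantom
#'
#' Unions a hollow sphere (outer radius `radius_mm`, wall `thickness_mm`,
#' default 1 mm) onto the phantom at a fixed attachment point on the flank of
#' the jaw block — a stylized unilateral tumor. The stored `truth_plane` is
#' left unchanged: it remains the symmetry plane of the unperturbed phantom,
#' which is the reference that robustness is measured against. If the
#' protrusion exits the grid, the grid is zero-padded (with a warning) and
#' the origin adjusted.
#'
#' @param ph A [phantom].
#' @param side `"left"` (+x, default) or `"right"` (-x).
#' @param radius_mm Outer radius in mm; 0 returns the phantom unchanged.
#'   Radii 5-50 mm are the intended range.
#' @param thickness_mm Shell wall thickness in mm (default 1).
#' @return The perturbed [phantom].
#' @export
add_protrusion <- function(ph, side = c("left", "right"), radius_mm,
                           thickness_mm = 1) {
  stopifnot(inherits(ph, "phantom"), radius_mm >= 0, thickness_mm > 0)
  side <- match.arg(side)
  if (radius_mm == 0) return(ph)
  if (radius_mm <= thickness_mm)
    stop("protrusion radius must exceed its shell thickness")
  ctr <- protrusion_attachment(ph$spec, side)
  grid <- ph$grid
  d <- dim(grid$occupancy)
  lo_need <- ctr - radius_mm
  hi_need <- ctr + radius_mm
  lo_pad <- pmax(0, ceiling((grid$origin - lo_need) / grid$spacing))
  hi_pad <- pmax(0, ceiling((hi_need - (grid$origin + d * grid$spacing)) /
                              grid$spacing))
  if (any(lo_pad > 0) || any(hi_pad > 0)) {
    warning("protrusion exits the grid; padding and adjusting origin")
    grid <- pad_grid(grid, lo_pad, hi_pad)
    d <- dim(grid$occupancy)
  }
  # only visit the voxel sub-box around the sphere
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, floor((ctr[ax] - radius_mm - grid$origin[ax]) /
                          grid$spacing[ax]) + 1L)
    hi <- min(d[ax], ceiling((ctr[ax] + radius_mm - grid$origin[ax]) /
                               grid$spacing[ax]))
    lo:hi
  })
  xs <- grid$origin[1] + (rng[[1]] - 0.5) * grid$spacing[1] - ctr[1]
  ys <- grid$origin[2] + (rng[[2]] - 0.5) * grid$spacing[2] - ctr[2]
  zs <- grid$origin[3] + (rng[[3]] - 0.5) * grid$spacing[3] - ctr[3]
  nx <- length(xs); nyy <- length(ys); nzz <- length(zs)
  R2 <- array(rep(xs^2, times = nyy * nzz), c(nx, nyy, nzz)) +
    array(rep(rep(ys^2, each = nx), times = nzz), c(nx, nyy, nzz)) +
    array(rep(zs^2, each = nx * nyy), c(nx, nyy, nzz))
  shell <- R2 <= radius_mm^2 & R2 > (radius_mm - thickness_mm)^2
  sub <- grid$occupancy[rng[[1]], rng[[2]], rng[[3]]]
  sub[shell] <- 1L
  occ <- grid$occupancy
  occ[rng[[1]], rng[[2]], rng[[3]]] <- sub
  ph$grid <- voxel_grid(occ, grid$spacing, grid$origin)
  ph
}

# Rotation matrix from extrinsic x-y-z rotations in degrees: Rz Ry Rx.
euler_rotation <- function(rot_deg) {
  r <- rot_deg * pi / 180
  Rx <- rotation_about_axis(c(1, 0, 0), r[1])
  Ry <- rotation_about_axis(c(0, 1, 0), r[2])
  Rz <- rotation_about_axis(c(0, 0, 1), r[3])
  Rz %*% Ry %*% Rx
}

#' Apply a rigid pose to a phantom
#'
#' Rotates (extrinsic x-y-z order, degrees, about the grid's physical center)
#' and translates the phantom. The occupancy is resampled by nearest neighbor
#' under the rigid map onto a new axis-aligned grid with the same spacing;
#' the truth plane and landmarks are transformed exactly (analytically), so
#' parameter-recovery tests can carry the ground truth through the pose.
#'
#' @param ph A [phantom].
#' @param rot_deg Rotation angles `(rx, ry, rz)` in degrees.
#' @param translation Translation (mm).
#' @return The posed [phantom].
#' @export
apply_rigid <- function(ph, rot_deg = c(0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(inherits(ph, "phantom"), length(rot_deg) == 3L,
            length(translation) == 3L, all(is.finite(c(rot_deg, translation))))
  grid <- ph$grid
  R <- euler_rotation(rot_deg)
  tr <- as.numeric(translation)
  d <- dim(grid$occupancy)
  ctr <- grid$origin + d * grid$spacing / 2
  fwd <- function(p) sweep(sweep(p, 2L, ctr) %*% t(R), 2L, ctr + tr, "+")

  corners <- as.matrix(expand.grid(x = c(0, d[1]), y = c(0, d[2]),
                                   z = c(0, d[3])))
  corners <- sweep(sweep(corners, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
  moved <- fwd(corners)
  lo <- apply(moved, 2, min)
  hi <- apply(moved, 2, max)
  nd <- as.integer(ceiling((hi - lo) / grid$spacing - 1e-9))
  new_origin <- lo

  xs <- new_origin[1] + (seq_len(nd[1]) - 0.5) * grid$spacing[1]
  ys <- new_origin[2] + (seq_len(nd[2]) - 0.5) * grid$spacing[2]
  zs <- new_origin[3] + (seq_len(nd[3]) - 0.5) * grid$spacing[3]
  q <- cbind(rep(xs, times = nd[2] * nd[3]),
             rep(rep(ys, each = nd[1]), times = nd[3]),
             rep(zs, each = nd[1] * nd[2]))
  # inverse map back into the source grid, nearest-neighbor lookup
  p <- sweep(sweep(q, 2L, ctr + tr) %*% R, 2L, ctr, "+")
  ijk <- floor(sweep(sweep(p, 2L, grid$origin, "-"), 2L, grid$spacing, "/")) + 1
  inside <- ijk[, 1] >= 1 & ijk[, 2] >= 1 & ijk[, 3] >= 1 &
    ijk[, 1] <= d[1] & ijk[, 2] <= d[2] & ijk[, 3] <= d[3]
  occ <- integer(prod(nd))
  lin <- (ijk[inside, 1] - 1) + d[1] * ((ijk[inside, 2] - 1) +
                                          d[2] * (ijk[inside, 3] - 1)) + 1
  occ[inside] <- grid$occupancy[lin]
  ph$grid <- voxel_grid(array(occ, nd), grid$spacing, new_origin)

  pl <- ph$truth_plane
  n_new <- drop(R %*% pl$normal)
  pt_old <- pl$anchor - pl$d * pl$normal
  ph$truth_plane <- plane_from_normal(n_new, point = drop(fwd(t(pt_old))),
                                      anchor = drop(fwd(t(pl$anchor))))
  lm <- ph$landmarks
  for (nm in names(lm)) lm[[nm]] <- drop(fwd(t(lm[[nm]])))
  ph$landmarks <- lm
  ph
}

#' Break the phantom's symmetry
#'
#' `unilateral_scale` stretches (or shrinks) one side of the phantom along
#' the truth-plane normal by `factor` (nearest-neighbor resampled), a
#' stand-in for hemifacial overgrowth; the stored truth plane is retained as
#' the nominal reference. `landmark_jitter` perturbs the landmarks with
#' isotropic Gaussian noise of standard deviation `factor` mm, emulating
#' operator variability in landmark identification; the grid is untouched.
#'
#' @param ph A [phantom].
#' @param mode `"unilateral_scale"` or `"landmark_jitter"`.
#' @param factor Scale factor in (0.5, 1.5) for `unilateral_scale`; jitter
#'   standard deviation in mm for `landmark_jitter`.
#' @param seed Integer seed (used by `landmark_jitter`); defaults to the
#'   phantom spec's seed.
#' @return The perturbed [phantom].
#' @export
add_asymmetry <- function(ph, mode = c("unilateral_scale", "landmark_jitter"),
                          factor, seed = ph$spec$seed) {
  stopifnot(inherits(ph, "phantom"), is.finite(factor))
  mode <- match.arg(mode)
  if (mode == "landmark_jitter") {
    stopifnot(factor >= 0)
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    lm <- ph$landmarks
    for (nm in names(lm)) lm[[nm]] <- lm[[nm]] + stats::rnorm(3, 0, factor)
    ph$landmarks <- lm
    return(ph)
  }
  if (factor <= 0.5 || factor >= 1.5)
    stop("unilateral scale factor must lie in (0.5, 1.5)")
  if (factor == 1) return(ph)
  grid <- ph$grid
  pl <- ph$truth_plane
  d <- dim(grid$occupancy)
  if (factor > 1) {  # the scaled side grows; pad along +normal
    centers_rng <- range(signed_distance(voxel_centers(grid), pl))
    extra <- (factor - 1) * max(0, centers_rng[2])
    pad_vox <- ceiling(abs(extra * pl$normal) / grid$spacing)
    grid <- pad_grid(grid, c(0, 0, 0), pad_vox)
    d <- dim(grid$occupancy)
  }
  xs <- grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 0.5) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 0.5) * grid$spacing[3]
  q <- cbind(rep(xs, times = d[2] * d[3]),
             rep(rep(ys, each = d[1]), times = d[3]),
             rep(zs, each = d[1] * d[2]))
  s <- signed_distance(q, pl)
  shift <- (1 - 1 / factor) * pmax(s, 0)
  p <- q - outer(shift, pl$normal)
  src_dim <- dim(ph$grid$occupancy)
  ijk <- floor(sweep(sweep(p, 2L, ph$grid$origin, "-"),
                     2L, ph$grid$spacing, "/")) + 1
  inside <- ijk[, 1] >= 1 & ijk[, 2] >= 1 & ijk[, 3] >= 1 &
    ijk[, 1] <= src_dim[1] & ijk[, 2] <= src_dim[2] & ijk[, 3] <= src_dim[3]
  occ <- integer(prod(d))
  lin <- (ijk[inside, 1] - 1) + src_dim[1] * ((ijk[inside, 2] - 1) +
                                                src_dim[2] * (ijk[inside, 3] - 1)) + 1
  occ[inside] <- ph$grid$occupancy[lin]
  ph$grid <- voxel_grid(array(occ, d), grid$spacing, grid$origin)
  ph
}
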