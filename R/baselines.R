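#' Named cephalometric landmarks
#'
#' The four landmarks of the landmark-based mid-sagittal plane: crista galli
#' (CG, most superior point of the crista galli), anterior nasal spine (ANS),
#' and the most inferior points of the right and left orbital rims
#' (OrR, OrL). Coordinates in mm.
#'
#' @param CG,ANS,OrR,OrL Length-3 numeric vectors (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(CG, ANS, OrR, OrL) {
  pts <- list(CG = CG, ANS = ANS, OrR = OrR, OrL = OrL)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (length(p) != 3L || !all(is.finite(p)))
      stop("landmark ", nm, " must be a finite 3D point")
    pts[[nm]] <- as.numeric(p)
  }
  structure(pts, class = "landmark_set")
}

#' Landmark-based symmetry plane (LSP)
#'
#' The clinical mid-sagittal plane through three feature points: CG, ANS and
#' the midpoint of the left and right orbitale. The midpoint makes the plane
#' invariant to swapping OrR and OrL.
#'
#' @param lm A [landmark_set].
#' @return A [sym_plane] through the three points, anchored at their
#'   centroid.
#' @export
landmark_plane <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  M <- (lm$OrR + lm$OrL) / 2
  u <- lm$ANS - lm$CG
  v <- M - lm$CG
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(n^2))
  # distance of M to the CG-ANS line as a collinearity diagnostic
  lu <- sqrt(sum(u^2))
  dist_to_line <- if (lu < 1e-12) sqrt(sum(v^2)) else nn / lu
  if (nn < 1e-9 * max(1, lu))
    stop(sprintf(
      "CG, ANS and the orbitale midpoint are collinear (midpoint is %.3g mm from the CG-ANS line); cannot define a plane",
      dist_to_line))
  anchor <- (lm$CG + lm$ANS + M) / 3
  plane_from_normal(n, point = lm$CG, anchor = anchor)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation Length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)),
            length(translation) == 3L, all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must have determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param points `n x 3` matrix (or length-3 vector) of points.
#' @param transform A [rigid_transform].
#' @return The transformed `n x 3` matrix.
#' @export
apply_transform <- function(points, transform) {
  p <- as_point_matrix(points)
  sweep(p %*% t(transform$rotation), 2L, transform$translation, "+")
}

# Least-squares rigid fit mapping source points onto matched target points
# (Kabsch / SVD).
kabsch_fit <- function(source, target) {
  sc <- colMeans(source)
  tc <- colMeans(target)
  H <- crossprod(sweep(source, 2L, sc), sweep(target, 2L, tc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, tc - drop(R %*% sc))
}

# Outward-agnostic surface normals by local PCA over the k nearest
# neighbours (sign is arbitrary; point-to-plane residuals square it away).
estimate_normals <- function(pts, k = 12L) {
  pts <- as_point_matrix(pts)
  k <- min(k, nrow(pts))
  if (k < 3L) stop("need at least 3 points to estimate normals")
  nb <- cpp_knn(pts, pts, k)$index
  t(vapply(seq_len(nrow(pts)), function(i) {
    nbh <- pts[nb[i, ], , drop = FALSE]
    eigen(stats::cov(nbh), symmetric = TRUE)$vectors[, 3]
  }, numeric(3)))
}

#' Iterative closest point rigid registration
#'
#' Alternates kd-tree closest-point correspondence with a rigid update until
#' the RMS residual changes by less than `tol` or `max_iter` iterations are
#' reached. With `method = "point"` (the default) the update is the
#' closed-form least-squares rigid fit (SVD-based) to the matched points and
#' the RMS correspondence distance is non-increasing across iterations. With
#' `method = "plane"` the update minimizes the point-to-plane residual
#' (distance along the target's surface normal, small-angle linearization),
#' which converges much better on smooth, densely sampled surfaces where
#' point-to-point correspondences slide tangentially.
#'
#' @param source,target `n x 3` point matrices (mm); the returned transform
#'   maps `source` onto `target`.
#' @param tol Convergence tolerance on the RMS change (mm); default 1e-6.
#' @param max_iter Maximum iterations; default 50.
#' @param method `"point"` (classic ICP) or `"plane"` (point-to-plane).
#' @param target_normals Optional `n x 3` unit normals for the target,
#'   required by `method = "plane"`; estimated by local PCA
#'   (12 nearest neighbours) when omitted.
#' @return A [rigid_transform] with attributes `rms` (final RMS residual)
#'   and `rms_history`.
#' @export
icp_register <- function(source, target, tol = 1e-6, max_iter = 50,
                         method = c("point", "plane"),
                         target_normals = NULL) {
  method <- match.arg(method)
  source <- as_point_matrix(source)
  target <- as_point_matrix(target)
  if (nrow(source) < 1L || nrow(target) < 1L) stop("point sets must be nonempty")
  if (!all(is.finite(source)) || !all(is.finite(target)))
    stop("point sets must be finite")
  stopifnot(tol > 0, max_iter >= 1)
  if (method == "plane" && is.null(target_normals))
    target_normals <- estimate_normals(target)
  tf <- rigid_transform(diag(3), c(0, 0, 0))
  rms_hist <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(source, tf)
    nn <- cpp_nn(target, moved)
    if (method == "point") {
      rms <- sqrt(mean(nn$distance^2))
      rms_hist <- c(rms_hist, rms)
      if (abs(prev - rms) < tol) break
      prev <- rms
      tf <- kabsch_fit(source, target[nn$index, , drop = FALSE])
    } else {
      q <- target[nn$index, , drop = FALSE]
      nq <- target_normals[nn$index, , drop = FALSE]
      r <- rowSums((moved - q) * nq)
      rms <- sqrt(mean(r^2))
      rms_hist <- c(rms_hist, rms)
      if (abs(prev - rms) < tol) break
      prev <- rms
      # rows [ (p x n)^T  n^T ] (omega, t) = -(p - q) . n
      cx <- cbind(moved[, 2] * nq[, 3] - moved[, 3] * nq[, 2],
                  moved[, 3] * nq[, 1] - moved[, 1] * nq[, 3],
                  moved[, 1] * nq[, 2] - moved[, 2] * nq[, 1])
      M <- cbind(cx, nq)
      sol <- tryCatch(solve(crossprod(M), crossprod(M, -r)),
                      error = function(e) qr.solve(M, -r))
      w <- sol[1:3]
      th <- sqrt(sum(w^2))
      dR <- if (th < 1e-14) diag(3) else rotation_about_axis(w / th, th)
      tf <- rigid_transform(dR %*% tf$rotation,
                            drop(dR %*% tf$translation) + sol[4:6])
    }
  }
  attr(tf, "rms") <- rms_hist[length(rms_hist)]
  attr(tf, "rms_history") <- rms_hist
  tf
}

#' PCA initial plane for the surface-based method
#'
#' A first guess at the mirror plane from the point cloud's principal axes:
#' the plane passes through the centroid, and its normal is the principal
#' axis whose mirror plane gives the lowest mean closest-point distance
#' between the mirrored and original clouds (each axis is scored once). This
#' removes the arbitrary choice of axis, a known failure mode of PCA
#' initialization on strongly asymmetric shapes.
#'
#' @param pts `n x 3` point matrix (mm), at least 3 non-collinear points.
#' @return A [sym_plane] through the centroid (`d = 0`).
#' @export
pca_initial_plane <- function(pts) {
  pts <- as_point_matrix(pts)
  if (nrow(pts) < 3L) stop("need at least 3 points")
  if (!all(is.finite(pts))) stop("points must be finite")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2L, ctr)
  C <- crossprod(cc) / nrow(pts)
  eg <- eigen(C, symmetric = TRUE)
  if (sum(eg$values > 1e-9 * max(eg$values, 1e-12)) < 2L)
    stop("degenerate point cloud: covariance rank < 2")
  scores <- vapply(1:3, function(k) {
    pl <- plane_from_normal(eg$vectors[, k], point = ctr)
    mirrored <- reflect_points(pts, pl)
    mean(cpp_nn(pts, mirrored)$distance)
  }, numeric(1))
  plane_from_normal(eg$vectors[, which.min(scores)], point = ctr)
}

# Extract the mirror normal of the rotoreflection A (orthogonal, det -1):
# its unit eigenvector at eigenvalue -1. `ref` fixes the sign.
reflection_normal <- function(A, ref) {
  eg <- eigen(A)
  k <- which.min(abs(eg$values + 1))
  n <- Re(eg$vectors[, k])
  n <- n / sqrt(sum(n^2))
  if (sum(n * ref) < 0) n <- -n
  n
}

#' Surface-based symmetry plane (SSP)
#'
#' The mirror-and-register comparator: starting from the PCA plane, the cloud
#' is split by the current plane, the smaller side is mirrored across it, the
#' mirrored points are ICP-registered onto the other side (point-to-plane
#' residuals by default, which converge reliably on smooth dense surface
#' clouds where point-to-point correspondences slide), and the plane
#' normal is updated from the ICP rotation (the composite of the current
#' reflection with the ICP rotation is itself nearly a reflection; its mirror
#' normal — the rotation of the current normal by half the ICP rotation
#' angle — becomes the new normal). The plane stays anchored at the PCA
#' centroid throughout: the ICP translation is discarded, on the assumption
#' that the symmetry plane passes through the center of the skeleton. The
#' outer loop runs a fixed number of times (default 10).
#'
#' @param pts `n x 3` point matrix (mm), e.g. deduplicated STL vertices or
#'   surface voxel centers.
#' @param n_outer Number of outer mirror-register-update iterations
#'   (default 10); 0 returns the initial plane unchanged.
#' @param icp_tol,icp_max_iter Inner ICP settings (see [icp_register]).
#' @param icp_method Inner registration residual, `"plane"` (default) or
#'   `"point"`; see [icp_register].
#' @param init_plane Optional starting plane; defaults to the PCA plane. The
#'   anchor stays at the cloud centroid either way.
#' @return A [sym_plane] through the cloud centroid.
#' @export
surface_symmetry_plane <- function(pts, n_outer = 10, icp_tol = 1e-6,
                                   icp_max_iter = 50,
                                   icp_method = c("plane", "point"),
                                   init_plane = NULL) {
  pts <- as_point_matrix(pts)
  icp_method <- match.arg(icp_method)
  stopifnot(n_outer >= 0)
  pl <- if (is.null(init_plane)) {
    pca_initial_plane(pts)
  } else {
    stopifnot(inherits(init_plane, "sym_plane"))
    plane_from_normal(init_plane$normal, point = colMeans(pts))
  }
  ctr <- pl$anchor
  if (n_outer == 0) return(pl)
  normals <- if (icp_method == "plane") estimate_normals(pts) else NULL
  for (it in seq_len(n_outer)) {
    s <- signed_distance(pts, pl)
    on_A <- s >= 0
    A_side <- pts[on_A, , drop = FALSE]
    B_side <- pts[!on_A, , drop = FALSE]
    if (nrow(A_side) == 0L || nrow(B_side) == 0L)
      stop(sprintf("iteration %d: the plane does not split the cloud (one side is empty)", it))
    # mirror the smaller side, deterministically
    if (nrow(B_side) <= nrow(A_side)) {
      mirrored <- reflect_points(B_side, pl)
      fixed <- A_side
      fixed_n <- if (is.null(normals)) NULL else normals[on_A, , drop = FALSE]
    } else {
      mirrored <- reflect_points(A_side, pl)
      fixed <- B_side
      fixed_n <- if (is.null(normals)) NULL else normals[!on_A, , drop = FALSE]
    }
    tf <- icp_register(mirrored, fixed, tol = icp_tol,
                       max_iter = icp_max_iter, method = icp_method,
                       target_normals = fixed_n)
    A_lin <- tf$rotation %*% reflection_matrix(pl$normal)
    n_new <- reflection_normal(A_lin, pl$normal)
    pl <- plane_from_normal(n_new, point = ctr)
  }
  pl
}
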