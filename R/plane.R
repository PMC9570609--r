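#' Symmetry plane in spherical parameterization
#'
#' A plane in physical (mm) coordinates, parameterized by the polar angle
#' `phi`, the azimuth `theta` and a signed offset `d` measured relative to an
#' anchor point. The unit normal is
#' `n(phi, theta) = (sin(phi) cos(theta), sin(phi) sin(theta), cos(phi))`
#' and the plane equation is `n . (x - anchor) + d = 0`. The search for the
#' optimal symmetry plane runs over `phi, theta` in `[0, pi]` and a bounded
#' `d`, which covers every plane orientation once (normals with a negative
#' y-component are equivalent to the flipped plane).
#'
#' @param phi Polar angle in radians.
#' @param theta Azimuth in radians.
#' @param d Signed offset (mm) from the anchor along the normal.
#' @param anchor Reference point (mm) relative to which `d` is measured;
#'   typically the foreground centroid of the volume under study.
#' @return An object of class `sym_plane` with fields `phi`, `theta`, `d`,
#'   `anchor` and the derived unit `normal`.
#' @examples
#' pl <- sym_plane(pi / 2, 0, 0)     # the plane x = 0
#' reflect_points(c(1, 0, 0), pl)    # -> (-1, 0, 0)
#' @export
sym_plane <- function(phi, theta, d = 0, anchor = c(0, 0, 0)) {
  stopifnot(is.numeric(phi), is.numeric(theta), is.numeric(d),
            length(phi) == 1L, length(theta) == 1L, length(d) == 1L,
            length(anchor) == 3L, all(is.finite(c(phi, theta, d, anchor))))
  n <- c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  structure(list(phi = phi, theta = theta, d = d,
                 anchor = as.numeric(anchor), normal = n),
            class = "sym_plane")
}

#' Construct a plane from a unit normal and a point it passes through
#'
#' The normal is canonicalized so that `theta` lies in `[0, pi]` (the normal's
#' y-component is made non-negative; for normals in the xz-plane the
#' x-component is made non-negative, falling back to a non-negative
#' z-component). The returned `d` is chosen so the plane passes through
#' `point` with offsets measured from `anchor`.
#'
#' @param normal Plane normal (any nonzero length; normalized internally).
#' @param point A point (mm) on the plane.
#' @param anchor Anchor for the `d` offset; defaults to `point` (so `d = 0`).
#' @return A `sym_plane`.
#' @export
plane_from_normal <- function(normal, point, anchor = point) {
  stopifnot(length(normal) == 3L, all(is.finite(normal)),
            length(point) == 3L, all(is.finite(point)))
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("normal must be nonzero")
  n <- normal / nn
  eps <- 1e-12
  flip <- if (abs(n[2]) > eps) n[2] < 0
          else if (abs(n[1]) > eps) n[1] < 0
          else n[3] < 0
  if (flip) n <- -n
  phi <- acos(max(-1, min(1, n[3])))
  theta <- atan2(n[2], n[1])
  if (theta < 0) theta <- 0  # guard fp noise at the boundary
  d <- -sum(n * (point - anchor))
  pl <- sym_plane(phi, theta, d, anchor)
  pl$normal <- n  # keep the exact canonical normal
  pl
}

#' @export
print.sym_plane <- function(x, ...) {
  cat(sprintf("symmetry plane: phi = %.4f rad (%.2f deg), theta = %.4f rad (%.2f deg), d = %.3f mm\n",
              x$phi, x$phi * 180 / pi, x$theta, x$theta * 180 / pi, x$d))
  cat(sprintf("  normal = (%.5f, %.5f, %.5f), anchor = (%.2f, %.2f, %.2f) mm\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$anchor[1], x$anchor[2], x$anchor[3]))
  invisible(x)
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  points
}

#' Signed distance from points to a plane
#'
#' Positive on the side the normal points toward.
#'
#' @param points An `n x 3` matrix (or length-3 vector) of points in mm.
#' @param plane A [sym_plane].
#' @return Numeric vector of signed distances (mm).
#' @export
signed_distance <- function(points, plane) {
  p <- as_point_matrix(points)
  drop(p %*% plane$normal) - sum(plane$normal * plane$anchor) + plane$d
}

#' Reflect points across a plane
#'
#' Mirror image of each point: `p - 2 (n . (p - anchor) + d) n`. Reflection is
#' an involution: applying it twice returns the original points.
#'
#' @inheritParams signed_distance
#' @return An `n x 3` matrix of reflected points.
#' @export
reflect_points <- function(points, plane) {
  p <- as_point_matrix(points)
  s <- signed_distance(p, plane)
  p - 2 * outer(s, plane$normal)
}

#' Angle between two planes
#'
#' The 3D angle between plane normals, insensitive to normal orientation:
#' `acos(|n1 . n2|)`, reported in degrees in `[0, 90]`.
#'
#' @param p1,p2 [sym_plane] objects.
#' @return Angle in degrees.
#' @export
plane_angle <- function(p1, p2) {
  d <- abs(sum(p1$normal * p2$normal))
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Read and write planes as JSON
#'
#' The JSON interchange format stores `phi_rad`, `theta_rad`, `d_mm` and
#' `anchor_mm`, plus the derived `normal` and a `point_mm` on the plane for
#' consumers that prefer point-normal form. Reading recovers the plane
#' exactly.
#'
#' @param plane A [sym_plane].
#' @param path File path.
#' @return `read_plane` returns a `sym_plane`; `write_plane` returns `path`
#'   invisibly.
#' @export
write_plane <- function(plane, path) {
  pt <- plane$anchor - plane$d * plane$normal
  obj <- list(phi_rad = plane$phi, theta_rad = plane$theta, d_mm = plane$d,
              anchor_mm = plane$anchor, normal = plane$normal, point_mm = pt)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plane
#' @export
read_plane <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("phi_rad", "theta_rad", "d_mm", "anchor_mm"))
    if (is.null(obj[[f]])) stop("plane file missing field: ", f)
  sym_plane(obj$phi_rad, obj$theta_rad, obj$d_mm, obj$anchor_mm)
}

# Rotation matrix from axis (unit) and angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Householder reflection matrix across the plane's normal direction.
reflection_matrix <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  diag(3) - 2 * tcrossprod(n)
}
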