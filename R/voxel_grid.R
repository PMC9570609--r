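#' Binary voxel grid with physical spacing
#'
#' The container whose symmetry is measured: a 3D binary occupancy array on an
#' axis-aligned grid with anisotropic physical spacing. Voxel `(i, j, k)`
#' (1-based in R) occupies the half-open physical box
#' `[origin + (i-1) s, origin + i s)` along each axis, so a point on a shared
#' face belongs to exactly one voxel; its center is `origin + (i - 1/2) s`.
#'
#' @param occupancy 3D array of 0/1 values (logical arrays are coerced).
#'   Index order is x (within-row), y (within-column), z (slice axis).
#' @param spacing Physical voxel size `(sx, sy, sz)` in mm; all positive. A
#'   scalar is recycled.
#' @param origin Physical position (mm) of the lower corner of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `voxel_grid` with fields `occupancy`, `spacing`,
#'   `origin` and the derived `n_foreground`.
#' @export
voxel_grid <- function(occupancy, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3L) stop("occupancy must be a 3D array")
  # plain integer array, shedding any class/attributes from readers
  occupancy <- array(as.integer(occupancy), dim(occupancy))
  if (anyNA(occupancy) || !all(occupancy == 0L | occupancy == 1L))
    stop("occupancy values must be exactly 0 or 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(is.finite(spacing)), all(spacing > 0),
            length(origin) == 3L, all(is.finite(origin)))
  structure(list(occupancy = occupancy,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 n_foreground = sum(occupancy)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("voxel grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, %d foreground voxels\n",
              x$origin[1], x$origin[2], x$origin[3], x$n_foreground))
  invisible(x)
}

#' Physical centers of foreground voxels
#'
#' @param grid A [voxel_grid].
#' @return An `n x 3` matrix of voxel-center coordinates in mm, one row per
#'   foreground voxel (array order).
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- which(grid$occupancy == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  out <- sweep(sweep(idx - 0.5, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
  dimnames(out) <- NULL
  out
}

#' Centroid of the foreground
#'
#' Arithmetic mean of foreground voxel centers in physical mm; the anchor used
#' for the plane offset `d` during the symmetry search.
#'
#' @param grid A [voxel_grid] with at least one foreground voxel.
#' @return A length-3 numeric vector (mm).
#' @export
grid_centroid <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grid$n_foreground < 1L) stop("grid has no foreground voxels")
  colMeans(voxel_centers(grid))
}

# Map physical points to 1-based voxel indices by half-open containment;
# rows outside the grid get NA.
points_to_indices <- function(grid, points) {
  p <- as_point_matrix(points)
  d <- dim(grid$occupancy)
  ijk <- floor(sweep(sweep(p, 2L, grid$origin, "-"), 2L, grid$spacing, "/")) + 1
  outside <- ijk[, 1] < 1 | ijk[, 2] < 1 | ijk[, 3] < 1 |
    ijk[, 1] > d[1] | ijk[, 2] > d[2] | ijk[, 3] > d[3]
  ijk[outside, ] <- NA_real_
  storage.mode(ijk) <- "integer"
  ijk
}

#' Threshold a scalar image slice to a binary mask
#'
#' Bone segmentation on CT slices: intensities greater than or equal to the
#' threshold become foreground (the comparison is inclusive so boundary
#' behavior is deterministic).
#'
#' @param image_slice 2D numeric matrix of intensities.
#' @param threshold Finite scalar threshold.
#' @return An integer 0/1 matrix of the same shape.
#' @export
threshold_to_mask <- function(image_slice, threshold) {
  if (!is.matrix(image_slice) || length(image_slice) == 0L)
    stop("image_slice must be a nonempty 2D matrix")
  stopifnot(length(threshold) == 1L, is.finite(threshold))
  (image_slice >= threshold) + 0L
}

#' Ordered stack of 2D binary slice masks
#'
#' The intermediate between a CT series and a voxel grid: per-slice binary
#' masks, the in-plane pixel spacing, and the physical z-position of each
#' slice.
#'
#' @param masks List of 2D binary matrices, all of one shape.
#' @param pixel_spacing In-plane spacing `(sx, sy)` in mm.
#' @param slice_positions Strictly increasing physical z (mm), one per mask.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(masks, pixel_spacing, slice_positions) {
  stopifnot(is.list(masks), length(masks) >= 1L,
            length(pixel_spacing) == 2L, all(pixel_spacing > 0),
            length(slice_positions) == length(masks),
            all(is.finite(slice_positions)))
  shp <- dim(masks[[1]])
  for (m in masks) {
    if (!is.matrix(m) || !identical(dim(m), shp))
      stop("all masks must share one 2D shape")
    if (!all(m == 0 | m == 1)) stop("masks must be binary (0/1)")
  }
  if (any(duplicated(slice_positions)))
    stop("duplicate slice positions")
  if (is.unsorted(slice_positions, strictly = TRUE))
    stop("slice_positions must be strictly increasing")
  structure(list(masks = masks,
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_positions = as.numeric(slice_positions)),
            class = "slice_stack")
}

#' Build a voxel grid from a slice stack
#'
#' Stacks per-slice masks into a 3D binary grid. The voxel height comes from
#' the inter-slice gaps: the target z-spacing defaults to the smallest gap,
#' and slices with non-uniform gaps are resampled onto the uniform z-grid by
#' nearest-slice assignment (nearest-neighbor preserves binarity; ties go to
#' the lower slice). Uniformly spaced stacks pass through losslessly.
#'
#' @param stack A [slice_stack] with at least 2 slices.
#' @param z_spacing Target uniform z-spacing (mm); default `NULL` uses the
#'   minimum inter-slice gap.
#' @return A [voxel_grid]. Its origin is the first slice's physical position
#'   (with the slice mask covering `[z0, z0 + sz)`).
#' @export
build_voxel_grid <- function(stack, z_spacing = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  zp <- stack$slice_positions
  if (length(zp) < 2L) stop("need at least 2 slices to define voxel height")
  gaps <- diff(zp)
  sz <- if (is.null(z_spacing)) min(gaps) else z_spacing
  stopifnot(sz > 0)
  z_new <- seq(zp[1], zp[length(zp)], by = sz)
  # nearest-slice assignment; ties broken toward the lower slice
  pick <- vapply(z_new, function(z) {
    dd <- abs(zp - z)
    which(dd == min(dd))[1]
  }, integer(1))
  shp <- dim(stack$masks[[1]])
  occ <- array(0L, dim = c(shp[1], shp[2], length(z_new)))
  for (k in seq_along(z_new)) occ[, , k] <- stack$masks[[pick[k]]] + 0L
  voxel_grid(occ,
             spacing = c(stack$pixel_spacing, sz),
             origin = c(0, 0, zp[1]))
}
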