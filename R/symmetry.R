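#' Count paired voxels under a candidate symmetry plane
#'
#' A foreground voxel is *paired* if its center, reflected across the plane,
#' lands inside the half-open box of some foreground voxel; reflections that
#' fall outside the grid count as unpaired. The symmetry ratio is the paired
#' fraction of the foreground.
#'
#' @param grid A [voxel_grid] with at least one foreground voxel.
#' @param plane A [sym_plane].
#' @return `paired_count` returns `list(paired =, total =)` with
#'   `total = n_foreground`; `symmetry_ratio` returns `paired / total`, a
#'   value in `[0, 1]`.
#' @export
paired_count <- function(grid, plane) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(plane, "sym_plane"))
  if (grid$n_foreground < 1L) stop("grid has no foreground voxels")
  centers <- voxel_centers(grid)
  paired <- cpp_paired_eval(centers, grid$occupancy, dim(grid$occupancy),
                            grid$spacing, grid$origin,
                            plane$normal, plane$d, plane$anchor)
  list(paired = paired, total = grid$n_foreground)
}

#' @rdname paired_count
#' @export
symmetry_ratio <- function(grid, plane) {
  pc <- paired_count(grid, plane)
  pc$paired / pc$total
}

#' Initial plane: median plane of the foreground bounding box
#'
#' The search starts from the plane with normal along the grid x-axis
#' (`phi = pi/2`, `theta = 0`) passing through the center of the foreground
#' bounding box, anchored at the foreground centroid.
#'
#' @param grid A [voxel_grid] with at least one foreground voxel.
#' @return A [sym_plane].
#' @export
initial_plane <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grid$n_foreground < 1L) stop("grid has no foreground voxels")
  centers <- voxel_centers(grid)
  mid_x <- (min(centers[, 1]) + max(centers[, 1])) / 2
  anchor <- colMeans(centers)
  n <- c(1, 0, 0)
  d <- -sum(n * (c(mid_x, anchor[2], anchor[3]) - anchor))
  sym_plane(pi / 2, 0, d, anchor)
}

# Lexicographic comparison key used for candidate selection: maximize paired,
# then minimize angle to the initial orientation, then minimize |d|.
osp_order <- function(paired, phi, theta, d, init_normal) {
  n <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  ang <- acos(pmin(1, abs(drop(n %*% init_normal))))
  order(-paired, ang, abs(d), phi, theta, d)
}

#' Find the optimal symmetry plane (OSP)
#'
#' Maximizes the symmetry ratio over the plane parameters
#' `(phi, theta) in [0, pi]^2` and `d in [-d_range, d_range]` mm by a
#' deterministic coarse-to-fine search. Stage 1 scans orientations on a
#' regular angular grid (optionally restricted to a cone around the initial
#' bounding-box plane) with `d` on a one-voxel grid; because the paired count
#' is sharply peaked in `d` (narrower than one voxel), each orientation's
#' best `d` is polished by a halving line search before orientations are
#' compared. Stage 2 runs an iterated local pattern search from each of the
#' `n_starts` best stage-1 candidates, halving steps until the angular step
#' is below `angle_tol` and the d-step below `d_tol`, and keeps the best
#' refined plane. The symmetry ratio is piecewise
#' constant in the plane parameters, so the optimizer is derivative-free by
#' construction. Ties in SR are broken by the smaller angle to the initial
#' plane, then the smaller `|d|`, making the result unique and reproducible.
#'
#' @param grid A [voxel_grid] with at least one foreground voxel.
#' @param coarse_deg Stage-1 angular step in degrees (default 3).
#' @param cone_deg Half-angle (degrees) of the orientation cone around the
#'   initial plane scanned in stage 1; default 180 scans the full domain.
#' @param d_range Half-width (mm) of the `d` domain around the anchor
#'   (default 80).
#' @param d_step Stage-1 step for `d` in mm; default one voxel
#'   (`min(spacing)`).
#' @param angle_tol,d_tol Refinement stopping tolerances (degrees, mm);
#'   defaults 0.1 degree and 0.1 mm.
#' @param n_starts Number of stage-1 candidates refined in stage 2
#'   (default 10).
#' @param keep_trace Keep the recorded evaluation trace (`data.frame` of
#'   plane parameters and SR per evaluation) in the result; default `TRUE`.
#' @return An object of class `osp_result`: `plane` (the OSP), `osr`
#'   (`paired / total` at the OSP), `paired`, `total`, `n_evaluations` and
#'   (optionally) `search_trace`.
#' @export
find_osp <- function(grid, coarse_deg = 3, cone_deg = 180, d_range = 80,
                     d_step = NULL, angle_tol = 0.1, d_tol = 0.1,
                     n_starts = 10, keep_trace = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grid$n_foreground < 1L) stop("grid has no foreground voxels")
  if (coarse_deg <= 0 || cone_deg <= 0 || d_range <= 0 ||
      angle_tol <= 0 || d_tol <= 0 || n_starts < 1)
    stop("search settings must be positive")
  if (is.null(d_step)) d_step <- min(grid$spacing)
  if (d_step <= 0) stop("search settings must be positive")

  init <- initial_plane(grid)
  anchor <- init$anchor
  centers <- voxel_centers(grid)
  dims <- dim(grid$occupancy)

  ## stage 1: regular scan ----------------------------------------------
  step <- coarse_deg * pi / 180
  ang <- seq(0, pi, by = step)
  if (abs(ang[length(ang)] - pi) > 1e-9) ang <- c(ang, pi)
  ori <- expand.grid(phi = ang, theta = ang)
  # drop duplicate orientations at the poles (theta is irrelevant there)
  at_pole <- abs(sin(ori$phi)) < 1e-12
  ori <- ori[!at_pole | ori$theta == 0, ]
  if (cone_deg < 180) {
    n_ori <- cbind(sin(ori$phi) * cos(ori$theta),
                   sin(ori$phi) * sin(ori$theta), cos(ori$phi))
    keep <- acos(pmin(1, abs(drop(n_ori %*% init$normal)))) <=
      cone_deg * pi / 180 + 1e-12
    ori <- ori[keep, ]
  }
  scan <- cpp_sr_scan(centers, grid$occupancy, dims, grid$spacing,
                      grid$origin, anchor, ori$phi, ori$theta,
                      d_step, d_range, d_tol)
  cand <- scan$best
  ord <- osp_order(cand$paired, cand$phi, cand$theta, cand$d, init$normal)
  starts <- utils::head(ord, n_starts)

  eval_one <- function(phi, theta, d) {
    n <- c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    cpp_paired_eval(centers, grid$occupancy, dims, grid$spacing, grid$origin,
                    n, d, anchor)
  }
  key <- function(cand) {
    n <- c(sin(cand$phi) * cos(cand$theta),
           sin(cand$phi) * sin(cand$theta), cos(cand$phi))
    c(cand$paired,
      -acos(min(1, abs(sum(n * init$normal)))),
      -abs(cand$d))
  }
  better <- function(a, b) {  # TRUE if key a > key b lexicographically
    ka <- key(a); kb <- key(b)
    for (i in seq_along(ka)) {
      if (ka[i] > kb[i] + 1e-12) return(TRUE)
      if (ka[i] < kb[i] - 1e-12) return(FALSE)
    }
    FALSE
  }

  ## stage 2: pattern search with step halving, from each start ---------
  trace2 <- list()
  refine <- function(best) {
    a_step <- step
    dd_step <- d_step / 2
    while (a_step > angle_tol * pi / 180 || dd_step > d_tol) {
      n_moves <- 0L
      repeat {
        if (n_moves >= 1000L) break  # safety cap per step level
        moves <- list(c(a_step, 0, 0), c(-a_step, 0, 0),
                      c(0, a_step, 0), c(0, -a_step, 0),
                      c(0, 0, dd_step), c(0, 0, -dd_step))
        cand_best <- NULL
        for (mv in moves) {
          phi <- best$phi + mv[1]; theta <- best$theta + mv[2]
          d <- best$d + mv[3]
          if (abs(d) > d_range) next
          paired <- eval_one(phi, theta, d)
          if (keep_trace)
            trace2[[length(trace2) + 1L]] <<- c(phi, theta, d, paired)
          cand <- list(phi = phi, theta = theta, d = d, paired = paired)
          if (better(cand, best) &&
              (is.null(cand_best) || better(cand, cand_best)))
            cand_best <- cand
        }
        if (is.null(cand_best)) break
        best <- cand_best
        n_moves <- n_moves + 1L
      }
      a_step <- a_step / 2
      dd_step <- dd_step / 2
    }
    best
  }
  best <- NULL
  for (k in starts) {
    refined <- refine(list(phi = cand$phi[k], theta = cand$theta[k],
                           d = cand$d[k], paired = cand$paired[k]))
    if (is.null(best) || better(refined, best)) best <- refined
  }

  plane <- plane_from_normal(
    c(sin(best$phi) * cos(best$theta),
      sin(best$phi) * sin(best$theta), cos(best$phi)),
    point = anchor - best$d * c(sin(best$phi) * cos(best$theta),
                                sin(best$phi) * sin(best$theta),
                                cos(best$phi)),
    anchor = anchor)
  total <- grid$n_foreground
  res <- list(plane = plane, osr = best$paired / total,
              paired = best$paired, total = total,
              n_evaluations = nrow(scan$coarse) + nrow(scan$best) +
                length(trace2))
  if (keep_trace) {
    t2 <- if (length(trace2)) do.call(rbind, trace2) else
      matrix(numeric(0), 0, 4)
    colnames(t2) <- c("phi", "theta", "d", "paired")
    tr <- rbind(data.frame(scan$coarse, stage = 1L),
                data.frame(scan$best, stage = 1L),
                data.frame(t2, stage = 2L))
    tr$sr <- tr$paired / total
    res$search_trace <- tr
  }
  structure(res, class = "osp_result")
}

#' @export
print.osp_result <- function(x, ...) {
  cat(sprintf("optimal symmetry plane (OSR = %.4f, %d / %d voxels paired, %d evaluations)\n",
              x$osr, x$paired, x$total, x$n_evaluations))
  print(x$plane)
  invisible(x)
}

#' Best-so-far curve of the OSP search
#'
#' Plots SR against evaluation index (stage-1 scan then stage-2 refinement),
#' with the running maximum overlaid, for auditing the search.
#'
#' @param x An `osp_result` produced with `keep_trace = TRUE`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.osp_result <- function(x, ...) {
  if (is.null(x$search_trace)) stop("result has no search trace")
  sr <- x$search_trace$sr
  graphics::plot(seq_along(sr), cummax(sr), type = "l", lwd = 2,
                 xlab = "evaluation", ylab = "best SR so far", ...)
  graphics::abline(h = x$osr, lty = 2, col = "grey50")
  invisible(x)
}
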