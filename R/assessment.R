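#' Split a model by a plane
#'
#' Partitions a voxel grid (classified by voxel center) or a point set into
#' the side the plane normal points toward (`A`, signed distance >= 0) and
#' the other side (`B`, signed distance < 0). Either part may be empty;
#' downstream operations check.
#'
#' @param model A [voxel_grid] or an `n x 3` point matrix.
#' @param plane A [sym_plane].
#' @return `list(A =, B =)` of the same type as `model`.
#' @export
split_by_plane <- function(model, plane) {
  stopifnot(inherits(plane, "sym_plane"))
  if (inherits(model, "voxel_grid")) {
    idx <- which(model$occupancy == 1L, arr.ind = TRUE)
    occA <- array(0L, dim(model$occupancy))
    occB <- array(0L, dim(model$occupancy))
    if (nrow(idx) > 0L) {
      centers <- sweep(sweep(idx - 0.5, 2L, model$spacing, "*"),
                       2L, model$origin, "+")
      s <- signed_distance(centers, plane)
      occA[idx[s >= 0, , drop = FALSE]] <- 1L
      occB[idx[s < 0, , drop = FALSE]] <- 1L
    }
    list(A = voxel_grid(occA, model$spacing, model$origin),
         B = voxel_grid(occB, model$spacing, model$origin))
  } else {
    p <- as_point_matrix(model)
    s <- signed_distance(p, plane)
    list(A = p[s >= 0, , drop = FALSE], B = p[s < 0, , drop = FALSE])
  }
}

#' Hausdorff distance between two point sets
#'
#' The largest distance from a point in one set to the closest point in the
#' other, taken over both directions:
#' `max(max_a min_b |a-b|, max_b min_a |a-b|)`. Symmetric in its arguments;
#' zero exactly when the sets coincide. Computed with a kd-tree.
#'
#' @param A,B Nonempty `n x 3` point matrices (mm).
#' @return Distance in mm.
#' @export
hausdorff <- function(A, B) {
  A <- as_point_matrix(A)
  B <- as_point_matrix(B)
  if (nrow(A) < 1L || nrow(B) < 1L) stop("point sets must be nonempty")
  max(max(cpp_nn(B, A)$distance), max(cpp_nn(A, B)$distance))
}

check_same_grid <- function(volA, volB) {
  stopifnot(inherits(volA, "voxel_grid"), inherits(volB, "voxel_grid"))
  if (!identical(dim(volA$occupancy), dim(volB$occupancy)) ||
      !isTRUE(all.equal(volA$spacing, volB$spacing)) ||
      !isTRUE(all.equal(volA$origin, volB$origin)))
    stop("volumes must share grid shape, spacing and origin")
  if (volA$n_foreground == 0L && volB$n_foreground == 0L)
    stop("both volumes are empty")
}

#' Jaccard and Dice similarity coefficients of two volumes
#'
#' Volume-overlap measures on a shared voxel grid: the Jaccard coefficient is
#' intersection over union, the Dice coefficient is twice the intersection
#' over the sum of the volumes. They are algebraically linked by
#' `DSC = 2 JSC / (1 + JSC)`.
#'
#' @param volA,volB [voxel_grid]s sharing shape, spacing and origin, not both
#'   empty.
#' @return A scalar in `[0, 1]`.
#' @export
jaccard <- function(volA, volB) {
  check_same_grid(volA, volB)
  inter <- sum(volA$occupancy & volB$occupancy)
  inter / (volA$n_foreground + volB$n_foreground - inter)
}

#' @rdname jaccard
#' @export
dice <- function(volA, volB) {
  check_same_grid(volA, volB)
  inter <- sum(volA$occupancy & volB$occupancy)
  2 * inter / (volA$n_foreground + volB$n_foreground)
}

#' Surface voxels of a binary volume
#'
#' Centers of face-exposed foreground voxels (those with at least one of the
#' six face neighbors background or outside the grid); the point sampling
#' used for Hausdorff distances on voxel data.
#'
#' @param grid A [voxel_grid].
#' @return An `n x 3` matrix of voxel centers (mm).
#' @export
surface_voxels <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- grid$occupancy
  d <- dim(occ)
  padded <- array(0L, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  nb <- padded[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
    padded[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
    padded[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
    padded[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
    padded[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
    padded[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(occ == 1L & nb < 6L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  sweep(sweep(idx - 0.5, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

# Re-bin physical points into a binary grid with the geometry of `like`
# (half-open containment; points outside the grid are dropped).
bin_points_to_grid <- function(points, like) {
  occ <- array(0L, dim(like$occupancy))
  ijk <- points_to_indices(like, points)
  ijk <- ijk[stats::complete.cases(ijk), , drop = FALSE]
  occ[ijk] <- 1L
  voxel_grid(occ, like$spacing, like$origin)
}

#' Split-mirror-assess a symmetry plane against a model
#'
#' The assessment protocol: the model is split into two parts by the plane,
#' side `B` is reflected across the plane onto side `A`, and the agreement is
#' scored three ways — Hausdorff distance between the surface points of `A`
#' and of reflected `B` (mm), and Jaccard/Dice overlap between the voxelized
#' `A` and reflected `B` (reflected voxel centers re-binned onto the source
#' grid by half-open containment). Which side is reflected is analytically
#' immaterial (reflection is an isometry); side `B` is used deterministically.
#'
#' @param model A [voxel_grid] with at least one foreground voxel.
#' @param plane A [sym_plane] that bisects the model.
#' @param surface Optional `n x 3` matrix of surface points (e.g. mesh
#'   vertices) used for the Hausdorff distance instead of face-exposed voxel
#'   centers.
#' @param method_label Provenance tag recorded in the report (e.g. `"OSP"`).
#' @param sr Optional symmetry ratio to carry into the report.
#' @return An object of class `assessment_report`: `hd_mm`, `jsc`, `dsc`,
#'   `method_label` and optionally `sr`. `as.data.frame` turns it into a
#'   one-row table.
#' @export
assess_plane <- function(model, plane, surface = NULL, method_label = "",
                         sr = NULL) {
  stopifnot(inherits(model, "voxel_grid"))
  if (model$n_foreground < 1L) stop("model has no foreground voxels")
  parts <- split_by_plane(model, plane)
  if (parts$A$n_foreground == 0L || parts$B$n_foreground == 0L)
    stop("plane does not bisect model")
  refB_centers <- reflect_points(voxel_centers(parts$B), plane)
  refB <- bin_points_to_grid(refB_centers, parts$A)
  jsc <- jaccard(parts$A, refB)
  dsc <- dice(parts$A, refB)
  if (is.null(surface)) {
    surf <- surface_voxels(model)
    ssplit <- split_by_plane(surf, plane)
  } else {
    ssplit <- split_by_plane(as_point_matrix(surface), plane)
  }
  if (nrow(ssplit$A) == 0L || nrow(ssplit$B) == 0L)
    stop("plane does not bisect model")
  hd <- hausdorff(ssplit$A, reflect_points(ssplit$B, plane))
  structure(list(hd_mm = hd, jsc = jsc, dsc = dsc,
                 method_label = method_label, sr = sr),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("symmetry assessment%s: HD = %.3f mm, JSC = %.4f, DSC = %.4f%s\n",
              if (nzchar(x$method_label)) paste0(" [", x$method_label, "]") else "",
              x$hd_mm, x$jsc, x$dsc,
              if (!is.null(x$sr)) sprintf(", SR = %.4f", x$sr) else ""))
  invisible(x)
}

#' @export
as.data.frame.assessment_report <- function(x, ...) {
  data.frame(method = x$method_label, hd_mm = x$hd_mm, jsc = x$jsc,
             dsc = x$dsc, sr = if (is.null(x$sr)) NA_real_ else x$sr)
}

# Exact two-sided sign-flip p-value for the Wilcoxon signed-rank statistic,
# valid with tied |differences| (average ranks): dynamic programming over the
# 2^n sign assignments using doubled ranks (integers even with .5 ties).
# Zero differences are dropped, as in the classical test.
signed_rank_exact_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled ranks, exact integers
  V2 <- sum(r2[d > 0])
  total <- sum(r2)
  # distribution of the doubled statistic over independent +/- signs
  counts <- rep(0, total + 1)  # counts[v+1] = #assignments with statistic v
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  p_le <- sum(probs[seq_len(V2 + 1)])
  p_ge <- sum(probs[(V2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

# Paired two-sided signed-rank p-value: exact sign-flip distribution for
# small n (handles ties exactly), stats::wilcox.test beyond that.
paired_signed_rank_p <- function(x, y, exact_max_n = 25L) {
  if (all(x == y)) return(1)
  if (sum(x != y) <= exact_max_n) return(signed_rank_exact_p(x, y))
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
}

#' Pairwise Wilcoxon signed-rank comparison of symmetry-plane methods
#'
#' Compares the per-case assessments (HD, JSC, DSC) of two or more
#' plane-generation methods with two-sided Wilcoxon signed-rank tests, one
#' per method pair and assessment, flagging significance at `alpha`. For up
#' to 25 informative pairs the p-value comes from the exact sign-flip
#' distribution of the signed-rank statistic (correct also under tied
#' differences); larger samples use [stats::wilcox.test]. Raw
#' p-values are reported by default; an optional Holm adjustment (across the
#' pairs within each assessment) can be switched on.
#'
#' @param reports A data.frame with columns `case`, `method` and at least one
#'   of `hd_mm`, `jsc`, `dsc`; every method must cover the identical set of
#'   cases (paired design, at least 6 cases).
#' @param alpha Significance level; default 0.05.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A data.frame with columns `comparison`, `assessment`, `n`,
#'   `p_value`, `significant`.
#' @export
compare_methods_wilcoxon <- function(reports, alpha = 0.05,
                                     adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(reports), all(c("case", "method") %in% names(reports)))
  metrics <- intersect(c("hd_mm", "jsc", "dsc"), names(reports))
  if (length(metrics) == 0L) stop("reports contain no assessment columns")
  methods <- unique(reports$method)
  if (length(methods) < 2L) stop("need at least 2 methods to compare")
  case_sets <- split(reports$case, reports$method)
  ref_cases <- sort(unique(reports$case))
  for (m in methods) {
    cs <- case_sets[[m]]
    if (anyDuplicated(cs) || !identical(sort(cs), ref_cases))
      stop("methods must cover the identical set of cases exactly once (unpaired design)")
  }
  if (length(ref_cases) < 6L) stop("need at least 6 paired cases")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  rows <- list()
  for (metric in metrics) {
    wide <- stats::reshape(
      reports[, c("case", "method", metric)],
      idvar = "case", timevar = "method", direction = "wide")
    wide <- wide[order(wide$case), , drop = FALSE]
    pvals <- vapply(pairs, function(pr) {
      paired_signed_rank_p(wide[[paste0(metric, ".", pr[1])]],
                           wide[[paste0(metric, ".", pr[2])]])
    }, numeric(1))
    if (adjust == "holm") pvals <- stats::p.adjust(pvals, "holm")
    rows[[metric]] <- data.frame(
      comparison = vapply(pairs, function(pr) paste(pr, collapse = " vs "),
                          character(1)),
      assessment = metric, n = length(ref_cases), p_value = pvals,
      significant = pvals < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
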