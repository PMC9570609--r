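# Shared fixtures, built once per test run.

# Small, fast phantom for unit tests (2 mm voxels, ~3k foreground voxels).
tiny_phantom <- function() {
  make_symmetric_phantom(phantom_spec(semi_axes = c(20, 26, 24),
                                      shell_mm = 3, spacing = 2,
                                      margin_mm = 4))
}

# The study-scale phantom (defaults: 1.5 mm voxels), cached.
default_phantom_cache <- new.env()
default_phantom <- function() {
  if (is.null(default_phantom_cache$ph))
    default_phantom_cache$ph <- make_symmetric_phantom(phantom_spec())
  default_phantom_cache$ph
}

# Random small binary grid with arbitrary spacing/origin.
random_grid <- function(dims = c(8, 8, 8), p = 0.3,
                        spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  occ <- array(as.integer(stats::runif(prod(dims)) < p), dims)
  if (sum(occ) == 0L) occ[1, 1, 1] <- 1L
  voxel_grid(occ, spacing, origin)
}

random_plane <- function(anchor = c(0, 0, 0), d_sd = 3) {
  sym_plane(stats::runif(1, 0, pi), stats::runif(1, 0, pi),
            stats::rnorm(1, 0, d_sd), anchor)
}

# Brute-force pairing oracle, independent of the compiled path: reflects
# every foreground center with plain arithmetic and locates the containing
# voxel by findInterval over the box edges (half-open convention).
oracle_paired_count <- function(grid, plane) {
  centers <- voxel_centers(grid)
  n <- plane$normal
  d <- dim(grid$occupancy)
  edges <- lapply(1:3, function(ax)
    grid$origin[ax] + (0:d[ax]) * grid$spacing[ax])
  paired <- 0L
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ]
    s <- sum(n * (p - plane$anchor)) + plane$d
    q <- p - 2 * s * n
    ijk <- vapply(1:3, function(ax)
      findInterval(q[ax], edges[[ax]], left.open = FALSE,
                   rightmost.closed = FALSE), numeric(1))
    if (all(ijk >= 1) && all(ijk <= d) &&
        grid$occupancy[ijk[1], ijk[2], ijk[3]] == 1L)
      paired <- paired + 1L
  }
  list(paired = paired, total = grid$n_foreground)
}

# The synthetic recreation of the degraded-2D paired-pixel example:
# 41 foreground pixels and a vertical candidate line through x = 8.5.
fig2_fixture <- function() {
  df <- utils::read.csv(system.file("extdata", "fig2_synthetic_slice.csv",
                                    package = "symplane"))
  occ <- array(0L, c(18, 12, 1))
  occ[cbind(df$col, df$row, 1L)] <- 1L
  list(grid = voxel_grid(occ),
       plane = plane_from_normal(c(1, 0, 0), point = c(8.5, 0, 0)))
}
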