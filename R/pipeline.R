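#' Run a symplane pipeline step
#'
#' The programmatic surface behind the `symplane` command-line script. Each
#' subcommand reads its inputs, runs the corresponding package function with
#' the configured settings, writes its artifacts, and returns the result
#' invisibly. All defaults are the documented function defaults; every
#' written JSON artifact embeds the effective configuration so reruns are
#' auditable and reproducible.
#'
#' Subcommands and their main config entries:
#' \describe{
#'   \item{`phantom`}{Generate a phantom. `spacing`, `protrusion_radius`,
#'     `protrusion_side`, `asymmetry_factor`, `seed`; outputs `out` (volume),
#'     `truth` (plane JSON), `landmarks` (CSV).}
#'   \item{`osp`}{`mask` (volume path), optional `threshold`; search settings
#'     `coarse_deg`, `cone_deg`, `d_range`, `d_step`; output `out` (plane
#'     JSON with OSR).}
#'   \item{`ssp`}{`mesh` (STL) or `mask`; `outer`, `icp_tol`, `icp_max_iter`;
#'     output `out`.}
#'   \item{`lsp`}{`landmarks` (CSV/JSON); output `out`.}
#'   \item{`assess`}{`mask`, `plane` (JSON), optional `mesh` for surface
#'     points, `label`; output `out` (report JSON).}
#'   \item{`compare`}{`reports` (directory of report JSONs); output `out`
#'     (CSV table of pairwise Wilcoxon p-values).}
#' }
#'
#' @param command One of `"phantom"`, `"osp"`, `"ssp"`, `"lsp"`, `"assess"`,
#'   `"compare"`.
#' @param config Named list of settings (see Details).
#' @return The computed object (phantom, `osp_result`, `sym_plane`,
#'   `assessment_report` or comparison data.frame), invisibly.
#' @export
run_pipeline <- function(command = c("phantom", "osp", "ssp", "lsp",
                                     "assess", "compare"),
                         config = list()) {
  command <- match.arg(command)
  cfg <- function(name, default = NULL) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  need <- function(name) {
    v <- config[[name]]
    if (is.null(v)) stop("config entry '", name, "' is required for '",
                         command, "'")
    v
  }
  stamp <- function(obj_path) {
    # append the effective config to a JSON artifact for auditability
    obj <- jsonlite::read_json(obj_path)
    obj$config <- config[order(names(config))]
    obj$command <- command
    jsonlite::write_json(obj, obj_path, auto_unbox = TRUE, digits = NA)
  }

  if (command == "phantom") {
    spec <- phantom_spec(spacing = cfg("spacing", 1.5),
                         seed = cfg("seed", 1L))
    ph <- make_symmetric_phantom(spec)
    r <- cfg("protrusion_radius", 0)
    if (r > 0) ph <- add_protrusion(ph, cfg("protrusion_side", "left"), r)
    fac <- cfg("asymmetry_factor", 1)
    if (fac != 1) ph <- add_asymmetry(ph, "unilateral_scale", fac)
    write_volume(ph$grid, need("out"))
    if (!is.null(cfg("truth"))) {
      write_plane(ph$truth_plane, cfg("truth"))
      stamp(cfg("truth"))
    }
    if (!is.null(cfg("landmarks"))) write_landmarks(ph$landmarks, cfg("landmarks"))
    return(invisible(ph))
  }

  if (command == "osp") {
    grid <- read_volume(need("mask"), threshold = cfg("threshold"))
    res <- find_osp(grid,
                    coarse_deg = cfg("coarse_deg", 3),
                    cone_deg = cfg("cone_deg", 180),
                    d_range = cfg("d_range", 80),
                    d_step = cfg("d_step"),
                    keep_trace = FALSE)
    write_plane(res$plane, need("out"))
    obj <- jsonlite::read_json(need("out"))
    obj$osr <- res$osr; obj$paired <- res$paired; obj$total <- res$total
    jsonlite::write_json(obj, need("out"), auto_unbox = TRUE, digits = NA)
    stamp(need("out"))
    return(invisible(res))
  }

  if (command == "ssp") {
    pts <- if (!is.null(cfg("mesh"))) {
      read_stl(cfg("mesh"))$vertices
    } else {
      surface_voxels(read_volume(need("mask"), threshold = cfg("threshold")))
    }
    pl <- surface_symmetry_plane(pts, n_outer = cfg("outer", 10),
                                 icp_tol = cfg("icp_tol", 1e-6),
                                 icp_max_iter = cfg("icp_max_iter", 50))
    write_plane(pl, need("out"))
    stamp(need("out"))
    return(invisible(pl))
  }

  if (command == "lsp") {
    lm <- read_landmarks(need("landmarks"))
    pl <- landmark_plane(lm)
    write_plane(pl, need("out"))
    stamp(need("out"))
    return(invisible(pl))
  }

  if (command == "assess") {
    grid <- read_volume(need("mask"), threshold = cfg("threshold"))
    pl <- read_plane(need("plane"))
    surface <- if (!is.null(cfg("mesh"))) read_stl(cfg("mesh"))$vertices
    rep <- assess_plane(grid, pl, surface = surface,
                        method_label = cfg("label", ""),
                        sr = symmetry_ratio(grid, pl))
    jsonlite::write_json(unclass(rep), need("out"), auto_unbox = TRUE,
                         digits = NA)
    stamp(need("out"))
    return(invisible(rep))
  }

  # compare: one report JSON per (case, method) in a directory
  files <- list.files(need("reports"), pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) stop("no report JSONs in ", need("reports"))
  rows <- lapply(sort(files), function(f) {
    obj <- jsonlite::read_json(f, simplifyVector = TRUE)
    data.frame(case = if (!is.null(obj$case)) obj$case else
                 sub("\\.json$", "", basename(f)),
               method = obj$method_label,
               hd_mm = obj$hd_mm, jsc = obj$jsc, dsc = obj$dsc)
  })
  tab <- compare_methods_wilcoxon(do.call(rbind, rows),
                                  alpha = cfg("alpha", 0.05),
                                  adjust = cfg("adjust", "none"))
  utils::write.csv(tab, need("out"), row.names = FALSE)
  invisible(tab)
}
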