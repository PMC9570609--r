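#' Read a volume into a voxel grid
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) via RNifti or NRRD (`.nrrd`, attached
#' header, `raw`/`ascii`/`gzip` encodings). Physical spacing and origin are
#' preserved: the stored transform's translation names the center of the
#' first voxel, and the grid origin is that center minus half a voxel.
#' Binary inputs (values 0/1 only) pass through untouched; scalar inputs
#' require a `threshold` and are binarized with the inclusive `>=` rule of
#' [threshold_to_mask].
#'
#' @param path Input file.
#' @param threshold Optional scalar threshold for non-binary volumes.
#' @return A [voxel_grid].
#' @export
read_volume <- function(path, threshold = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
    sp <- RNifti::pixdim(img)[1:3]
    xf <- RNifti::xform(img)
    if (max(abs(xf[1:3, 1:3] - diag(sp))) > 1e-4)
      stop("only axis-aligned volumes with positive-diagonal orientation are supported")
    origin <- xf[1:3, 4] - sp / 2
  } else if (grepl("\\.nrrd$", lower)) {
    v <- read_nrrd(path)
    arr <- v$array; sp <- v$spacing; origin <- v$origin
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .nrrd): ", path)
  }
  vals <- unique(as.vector(arr))
  if (all(vals %in% c(0, 1))) {
    storage.mode(arr) <- "integer"
    return(voxel_grid(arr, sp, origin))
  }
  if (is.null(threshold))
    stop("volume is not binary; a threshold is required")
  voxel_grid((arr >= threshold) + 0L, sp, origin)
}

#' Write a binary voxel grid
#'
#' Writes NIfTI (via RNifti, 8-bit unsigned) or NRRD (attached header, raw
#' little-endian encoding) depending on the file extension. Round-trips
#' occupancy, spacing and origin exactly.
#'
#' @param grid A [voxel_grid].
#' @param path Output file (`.nii`, `.nii.gz` or `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(grid$occupancy)
    RNifti::pixdim(img) <- grid$spacing
    m <- diag(c(grid$spacing, 1))
    m[1:3, 4] <- grid$origin + grid$spacing / 2
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (grepl("\\.nrrd$", lower)) {
    write_nrrd(grid$occupancy, grid$spacing, grid$origin, path)
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .nrrd): ", path)
  }
  invisible(path)
}

# -- minimal NRRD (attached header, 3D) --------------------------------------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stop("NRRD header missing field: ", f)
    fields[[f]]
  }
  dimension <- as.integer(need("dimension"))
  if (dimension != 3L) stop("only 3D NRRD volumes are supported")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  typ <- need("type")
  enc <- need("encoding")
  spacing <- if (!is.null(fields[["spacings"]])) {
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(dirs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    if (max(abs(m - diag(diag(m)))) > 1e-9)
      stop("only axis-aligned NRRD space directions are supported")
    diag(m)
  } else stop("NRRD header missing field: spacings or space directions")
  origin <- if (!is.null(fields[["space origin"]])) {
    as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]]) -
      spacing / 2
  } else c(0, 0, 0)
  n <- prod(sizes)
  rtype <- switch(typ,
                  "uchar" = , "unsigned char" = , "uint8" = list(what = "integer", size = 1, signed = FALSE),
                  "short" = , "int16" = list(what = "integer", size = 2, signed = TRUE),
                  "int" = , "int32" = list(what = "integer", size = 4, signed = TRUE),
                  "float" = list(what = "numeric", size = 4, signed = TRUE),
                  "double" = list(what = "numeric", size = 8, signed = TRUE),
                  stop("unsupported NRRD type: ", typ))
  vals <- if (enc == "raw") {
    readBin(con, rtype$what, n = n, size = rtype$size, signed = rtype$signed,
            endian = "little")
  } else if (enc %in% c("gzip", "gz")) {
    raw_rest <- readBin(con, "raw", n = file.info(path)$size)
    gcon <- gzcon(rawConnection(raw_rest))
    on.exit(close(gcon), add = TRUE)
    readBin(gcon, rtype$what, n = n, size = rtype$size, signed = rtype$signed,
            endian = "little")
  } else if (enc %in% c("ascii", "txt", "text")) {
    scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data: expected ", n,
                              " values, got ", length(vals))
  list(array = array(vals, sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(arr, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# written by symplane",
           "type: uchar",
           "dimension: 3",
           "space: left-posterior-superior",
           sprintf("sizes: %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                   spacing[1], spacing[2], spacing[3]),
           "endian: little",
           "encoding: raw",
           sprintf("space origin: (%g,%g,%g)",
                   origin[1] + spacing[1] / 2, origin[2] + spacing[2] / 2,
                   origin[3] + spacing[3] / 2),
           "")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.raw(as.vector(arr)), con)
  invisible(path)
}

# -- STL ---------------------------------------------------------------------

#' Read a triangle mesh from STL
#'
#' Supports both the binary and ASCII STL dialects. Vertices are
#' deduplicated by exact coordinate match; the triangle count is preserved.
#'
#' @param path STL file.
#' @return A list with `vertices` (`n x 3` matrix of unique vertices, mm) and
#'   `triangles` (`m x 3` integer matrix of 1-based vertex indices).
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (size < 15) stop("truncated STL file (", size, " bytes)")
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(size, 512))
  close(con)
  is_ascii <- grepl("^\\s*solid", rawToChar(head_raw[1:min(80, length(head_raw))])) &&
    grepl("facet", rawToChar(head_raw), fixed = TRUE)
  tri_pts <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  n_tri <- nrow(tri_pts) / 3
  if (n_tri == 0) stop("empty STL (no facets): ", path)
  key <- apply(tri_pts, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  vertices <- tri_pts[uniq, , drop = FALSE]
  index <- match(key, key[uniq])
  triangles <- matrix(index, ncol = 3, byrow = TRUE)
  dimnames(vertices) <- NULL
  list(vertices = vertices, triangles = triangles)
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n_tri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * n_tri
  if (size < expected)
    stop("truncated binary STL: expected ", expected, " bytes, file has ",
         size, " (truncation at byte offset ", size, ")")
  out <- matrix(0, 3 * n_tri, 3)
  for (i in seq_len(n_tri)) {
    v <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    out[(3 * i - 2):(3 * i), ] <- matrix(v[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", n = 2)
  }
  out
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0) stop("empty STL (no facets): ", path)
  if (length(vl) %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3")
  m <- t(vapply(vl, function(s)
    as.numeric(strsplit(trimws(sub("^\\s*vertex\\s+", "", s)), "\\s+")[[1]]),
    numeric(3)))
  dimnames(m) <- NULL
  m
}

#' Write a triangle mesh as ASCII STL
#'
#' @param vertices `n x 3` matrix of vertex coordinates (mm).
#' @param triangles `m x 3` integer matrix of 1-based vertex indices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(vertices, triangles, path) {
  vertices <- as_point_matrix(vertices)
  lines <- c("solid symplane")
  for (i in seq_len(nrow(triangles))) {
    tri <- vertices[triangles[i, ], , drop = FALSE]
    u <- tri[2, ] - tri[1, ]; v <- tri[3, ] - tri[1, ]
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    lines <- c(lines,
               sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
               "    outer loop",
               sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
               "    endloop",
               "  endfacet")
  }
  writeLines(c(lines, "endsolid symplane"), path)
  invisible(path)
}

# -- landmarks ---------------------------------------------------------------

#' Read and write landmark files
#'
#' Landmarks are exchanged as CSV with columns `name,x,y,z` (mm) or as JSON
#' mapping names to `[x, y, z]` arrays. Names are matched case-insensitively
#' among CG, ANS, OrR, OrL.
#'
#' @param path Landmark file (`.csv` or `.json`).
#' @return `read_landmarks` returns a [landmark_set]; `write_landmarks`
#'   returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", tolower(path))) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- data.frame(name = names(obj),
                     t(vapply(obj, as.numeric, numeric(3))))
    names(df) <- c("name", "x", "y", "z")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("name", "x", "y", "z") %in% names(df)))
      stop("landmark CSV must have columns name,x,y,z")
  }
  pick <- function(nm) {
    i <- which(toupper(df$name) == toupper(nm))
    if (length(i) != 1L) stop("landmark file must name ", nm, " exactly once")
    as.numeric(df[i, c("x", "y", "z")])
  }
  landmark_set(CG = pick("CG"), ANS = pick("ANS"),
               OrR = pick("OrR"), OrL = pick("OrL"))
}

#' @rdname read_landmarks
#' @param lm A [landmark_set].
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(name = names(lm),
                   t(vapply(unclass(lm), identity, numeric(3))))
  names(df) <- c("name", "x", "y", "z")
  if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(unclass(lm), path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
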