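# Regular 3-D scalar fields (density, mean, SD, smoothed SD) with OpenDX
# import/export and trilinear sampling. Grids are isotropic: one spacing in
# Angstrom for all three axes; node (i, j, k) sits at
# origin + (i-1, j-1, k-1) * spacing.

#' Construct a regular 3-D scalar grid
#'
#' @param origin Numeric length-3, world position (Angstrom) of node (1,1,1).
#' @param spacing Positive voxel edge length, Angstrom (isotropic).
#' @param dims Integer length-3 node counts, each at least 1.
#' @param values Array of dimension `dims` (default all zero).
#' @return A `scalar_grid` object.
#' @export
scalar_grid <- function(origin, spacing, dims, values = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop_surfplast("grid dims must be three integers >= 1", "domain_error")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop_surfplast("grid spacing must be a positive scalar", "domain_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop_surfplast("grid origin must be a finite length-3 vector",
                   "domain_error")
  }
  if (is.null(values)) values <- array(0, dim = dims)
  if (!identical(as.integer(dim(values)), dims)) {
    stop_surfplast("values array does not match dims", "dimension_error")
  }
  if (any(!is.finite(values))) {
    stop_surfplast("grid values must be finite", "domain_error")
  }
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, values = values),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf(
    "<scalar_grid> %d x %d x %d nodes, spacing %g A, origin (%g, %g, %g)\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing,
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values in [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# Shared geometry enclosing a coordinate bounding box plus padding.
grid_geometry_from_box <- function(lo, hi, spacing, padding) {
  origin <- lo - padding
  dims <- pmax(1L, as.integer(ceiling((hi + padding - origin) / spacing)) + 1L)
  scalar_grid(origin, spacing, dims)
}

#' Grid geometry enclosing an ensemble (or coordinate matrix) plus padding
#'
#' @param x A `structure_ensemble` or an `N x 3` coordinate matrix.
#' @param spacing Voxel size, Angstrom.
#' @param padding Margin added on every side of the bounding box, Angstrom.
#' @return An empty `scalar_grid` defining origin/spacing/dims.
#' @export
grid_geometry <- function(x, spacing = 0.5, padding = 6) {
  if (inherits(x, "structure_ensemble")) {
    lo <- apply(x$coords, 3, min)
    hi <- apply(x$coords, 3, max)
  } else {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
  }
  grid_geometry_from_box(lo, hi, spacing, padding)
}

# World coordinates of grid nodes along one axis.
grid_axis <- function(grid, d) {
  grid$origin[d] + (seq_len(grid$dims[d]) - 1) * grid$spacing
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(a$dims, b$dims) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$spacing - b$spacing) < tol
}

#' Trilinear interpolation of a grid at world points
#'
#' @param grid A `scalar_grid`.
#' @param points `M x 3` matrix of world coordinates (Angstrom).
#' @return Numeric length-M vector of interpolated values.
#' @export
interp_trilinear <- function(grid, points) {
  points <- matrix(points, ncol = 3L)
  # fractional node coordinates, 0-based
  f <- sweep(sweep(points, 2, grid$origin), 2, grid$spacing, "/")
  out <- numeric(nrow(points))
  eps <- 1e-9
  for (d in 1:3) {
    bad <- f[, d] < -eps | f[, d] > grid$dims[d] - 1 + eps
    if (any(bad)) {
      stop_surfplast(sprintf(
        "point %d lies outside the grid along axis %d", which(bad)[1], d),
        "boundary_error")
    }
  }
  i0 <- pmin(pmax(floor(f), 0), matrix(rep(grid$dims - 2L, each = nrow(f)),
                                       ncol = 3L))
  i0 <- pmax(i0, 0)
  w <- f - i0
  v <- grid$values
  idx <- function(dx, dy, dz) {
    cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)
  }
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ww <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    out <- out + ww * v[idx(dx, dy, dz)]
  }
  out
}

# ---- OpenDX ----------------------------------------------------------------

#' Write a grid as an OpenDX scalar field
#'
#' Produces the `.dx` layout understood by PyMOL, VMD and Chimera
#' (gridpositions / gridconnections / data follows, z varying fastest).
#'
#' @param grid A `scalar_grid`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dx_grid <- function(grid, path) {
  if (!inherits(grid, "scalar_grid")) {
    stop_surfplast("`grid` must be a scalar_grid", "domain_error")
  }
  d <- grid$dims
  n <- prod(d)
  # DX stores x slowest, z fastest
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  pad <- (-length(vals)) %% 3L
  if (pad > 0) vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(sprintf("%.9e", vals), ncol = 3L, byrow = TRUE)
  rows <- apply(m, 1, function(r) paste(r[!grepl("NA", r)], collapse = " "))
  header <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.9g %.9g %.9g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.9g 0 0", grid$spacing),
    sprintf("delta 0 %.9g 0", grid$spacing),
    sprintf("delta 0 0 %.9g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows", n))
  footer <- c("attribute \"dep\" string \"positions\"",
              "object \"density\" class field",
              "component \"positions\" value 1",
              "component \"connections\" value 2",
              "component \"data\" value 3")
  ok <- tryCatch({
    writeLines(c(header, rows, footer), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop_surfplast(sprintf("cannot write '%s'", path), "io_error")
  }
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx_grid()]
#'
#' @param path Path to a `.dx` file with an isotropic diagonal delta.
#' @return A `scalar_grid`.
#' @export
read_dx_grid <- function(path) {
  if (!file.exists(path)) {
    stop_surfplast(sprintf("file '%s' does not exist", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  cl <- grep("gridpositions counts", lines, value = TRUE)[1]
  if (is.na(cl)) stop_surfplast("not an OpenDX grid file", "parse_error")
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", cl)), "\\s+")[[1]])
  ol <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", ol)), "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  dm <- t(vapply(dl, function(l) {
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- dm[1, 1]
  if (any(abs(dm - diag(rep(spacing, 3))) > 1e-9 * max(1, spacing))) {
    stop_surfplast("only isotropic diagonal deltas are supported",
                   "parse_error")
  }
  start <- grep("data follows", lines) + 1L
  n <- prod(dims)
  vals <- numeric(0)
  i <- start
  while (length(vals) < n && i <= length(lines)) {
    row <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (any(is.na(row))) break
    vals <- c(vals, row)
    i <- i + 1L
  }
  if (length(vals) < n) {
    stop_surfplast("truncated OpenDX data section", "parse_error")
  }
  arr <- aperm(array(vals[seq_len(n)], dim = rev(dims)), c(3, 2, 1))
  scalar_grid(origin, spacing, dims, arr)
}

#' Write a triangle mesh as a Wavefront OBJ file
#'
#' @param mesh List with `vertices` (`M x 3`, Angstrom) and `faces`
#'   (`K x 3`, 1-based), as returned by [extract_isosurface()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obj_mesh <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}
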