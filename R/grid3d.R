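#' 3D scalar grid
#'
#' The basic geo-referenced container of the engine: a scalar field sampled
#' at voxel centers on a regular axis-aligned grid. The frame is
#' right-handed, in mm, with the isocenter at the origin; `origin` is the
#' position of the center of voxel `(1,1,1)` (R indexing; the voxel indexed
#' `(0,0,0)` in 0-based conventions). Values are stored in an `nx x ny x nz`
#' array, x-fastest.
#'
#' @param values numeric 3D array, or a scalar to fill a grid of dimension
#'   `dims`.
#' @param spacing voxel spacing in mm; scalar (isotropic) or length-3.
#' @param origin mm position of the first voxel center, length-3.
#' @param dims integer triple, required only when `values` is a scalar.
#' @return An object of class `grid3d` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- grid3d(0, spacing = 2.5, origin = c(-10, -10, -10), dims = c(9, 9, 9))
#' dim(g$values)
#' @export
grid3d <- function(values, spacing, origin, dims = NULL) {
  if (length(values) == 1L && !is.null(dims)) {
    values <- array(as.numeric(values), dim = as.integer(dims))
  }
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite mm values")
  if (any(dim(values) < 1L)) stop("grid dims must be >= 1")
  # NaN marks not-evaluated voxels (e.g. gamma maps below the dose
  # cutoff); NA and infinities are always errors
  bad <- (is.na(values) & !is.nan(values)) | is.infinite(values)
  if (any(bad)) stop("grid values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  values in [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

grid_dims <- function(grid) dim(grid$values)

#' Voxel-center coordinates of a grid axis
#'
#' @param grid a [grid3d()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of voxel-center positions in mm.
#' @export
grid_axis <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Trilinear interpolation of a grid at arbitrary points
#'
#' Points outside the grid (beyond the outermost voxel centers) return `NA`
#' unless `rule = "clamp"`, which clamps to the edge value.
#'
#' @param grid a [grid3d()].
#' @param points n x 3 matrix of mm positions (or length-3 vector).
#' @param rule `"na"` or `"clamp"` for out-of-grid points.
#' @return numeric vector of interpolated values.
#' @export
grid_sample <- function(grid, points, rule = c("na", "clamp")) {
  rule <- match.arg(rule)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  storage.mode(points) <- "double"
  cpp_trilinear(grid$values, grid$spacing, grid$origin, points,
                rule == "clamp")
}

#' Total mass-like integral of a field over a density volume
#'
#' Computes `sum(field * ED * voxel_volume)` in relative units
#' (g when ED is read as g/cm^3-equivalent); used for energy-conservation
#' bookkeeping between TERMA and dose.
#'
#' @param grid a [grid3d()] field (e.g., dose or TERMA).
#' @param density a [density_volume()] on the same grid.
#' @return scalar.
#' @export
mass_weighted_sum <- function(grid, density) {
  stopifnot(all(dim(grid$values) == dim(density$grid$values)))
  vvol <- prod(grid$spacing) / 1000  # cm^3
  sum(grid$values * density$grid$values) * vvol
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
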