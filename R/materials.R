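#' The 16 photon energy bins of the engine (MeV)
#'
#' All spectra and radiological-property tables in the package are
#' discretized on these bin energies, spanning the megavoltage range of
#' clinical linacs (0.25 to 15 MeV).
#'
#' @return numeric vector of 16 strictly increasing energies in MeV.
#' @export
energy_bins <- function() {
  c(0.25, 0.5, 0.75, 1.0, 1.25, 1.5, 2.0, 2.5,
    3.0, 4.0, 5.0, 6.0, 8.0, 10.0, 12.5, 15.0)
}

#' Surrogate nine-material radiological property table
#'
#' Loads the versioned material table shipped with the package
#' (`extdata/materials_surrogate_v1.csv`): nine materials spanning air to a
#' metal surrogate, each with a reference relative electron density and
#' mass attenuation / mass energy-absorption coefficients (cm^2/g) at the 16
#' engine energy bins. Water is one of the nine, with reference ED exactly
#' 1.0. The vendor material set is proprietary, so these are surrogate
#' values derived from standard published photon cross-section compilations
#' for water with per-material scale factors.
#'
#' @return list with `names`, `reference_ed` (sorted increasing),
#'   `mu_over_rho` (9 x 16), `muen_over_rho` (9 x 16).
#' @export
material_table <- function() {
  tbl <- get0("materials", envir = .ccdose_env)
  if (!is.null(tbl)) return(tbl)
  path <- system.file("extdata", "materials_surrogate_v1.csv",
                      package = "ccdose", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  ord <- order(df$reference_ed)
  df <- df[ord, ]
  mu <- as.matrix(df[, grepl("^mu_", names(df))])
  muen <- as.matrix(df[, grepl("^muen_", names(df))])
  stopifnot(ncol(mu) == 16L, ncol(muen) == 16L, nrow(df) == 9L,
            any(df$name == "water"))
  tbl <- list(names = df$name, reference_ed = df$reference_ed,
              mu_over_rho = mu, muen_over_rho = muen)
  assign("materials", tbl, envir = .ccdose_env)
  tbl
}

#' Interpolate radiological coefficients at a relative electron density
#'
#' Locates the pair of materials whose reference electron densities bracket
#' `ed` and linearly interpolates every energy bin of both coefficient sets;
#' outside the nine-material ED range the nearest material's coefficients
#' are used unchanged. At `ed = 1` this returns exactly the water row.
#'
#' @param ed relative electron density (water = 1), scalar or vector, >= 0.
#' @return for scalar `ed`, list with `mu_over_rho` and `muen_over_rho`
#'   (16 each); for vector `ed`, list of two `length(ed) x 16` matrices.
#' @examples
#' material_blend(1.0)$mu_over_rho  # water coefficients
#' @export
material_blend <- function(ed) {
  if (any(!is.finite(ed)) || any(ed < 0)) stop("`ed` must be >= 0")
  tbl <- material_table()
  ref <- tbl$reference_ed
  edc <- pmin(pmax(ed, ref[1]), ref[length(ref)])
  i <- findInterval(edc, ref, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(ref) - 1L)
  w <- (edc - ref[i]) / (ref[i + 1L] - ref[i])
  mu <- (1 - w) * tbl$mu_over_rho[i, , drop = FALSE] +
    w * tbl$mu_over_rho[i + 1L, , drop = FALSE]
  muen <- (1 - w) * tbl$muen_over_rho[i, , drop = FALSE] +
    w * tbl$muen_over_rho[i + 1L, , drop = FALSE]
  if (length(ed) == 1L)
    list(mu_over_rho = unname(drop(mu)), muen_over_rho = unname(drop(muen)))
  else list(mu_over_rho = unname(mu), muen_over_rho = unname(muen))
}

#' CT-number to relative electron density conversion table
#'
#' @param hu CT numbers (HU), strictly increasing, at least 2 entries.
#' @param ed relative electron densities, >= 0, same length.
#' @return object of class `ct_to_ed_table`.
#' @export
ct_to_ed_table <- function(hu, ed) {
  if (length(hu) < 2L || length(hu) != length(ed))
    stop("CT-to-ED table needs >= 2 (hu, ed) pairs of equal length")
  if (any(diff(hu) <= 0)) stop("CT numbers must be strictly increasing")
  if (any(ed < 0)) stop("electron densities must be >= 0")
  structure(list(hu = as.numeric(hu), ed = as.numeric(ed)),
            class = "ct_to_ed_table")
}

#' A generic commissioning-style CT-to-ED table
#'
#' Three-node table mapping -1000 HU to ED 0, 0 HU to water, and a bone-like
#' slope above water. Adequate for the synthetic phantoms in this package.
#' @return a [ct_to_ed_table()].
#' @export
default_ct_table <- function() {
  ct_to_ed_table(hu = c(-1000, 0, 1000, 3000), ed = c(0, 1, 1.90, 3.2))
}

#' Voxelized relative electron density
#'
#' @param grid [grid3d()] of relative electron density (water = 1).
#' @param body_mask logical array of the same dims flagging inside-patient
#'   voxels; defaults to `ED > 0.05`.
#' @return object of class `density_volume` with fields `grid`, `body_mask`.
#' @export
density_volume <- function(grid, body_mask = NULL) {
  stopifnot(inherits(grid, "grid3d"))
  if (any(grid$values < 0)) stop("electron density must be >= 0")
  if (is.null(body_mask)) body_mask <- grid$values > 0.05
  stopifnot(is.logical(body_mask), all(dim(body_mask) == dim(grid$values)))
  structure(list(grid = grid, body_mask = body_mask),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat("<density_volume>\n"); print(x$grid)
  cat(sprintf("  body: %d voxels (%.1f%%)\n", sum(x$body_mask),
              100 * mean(x$body_mask)))
  invisible(x)
}

#' Structure set: named masks with optional density overrides
#'
#' @param structures list of entries `list(name=, mask=, density_override=)`
#'   where `mask` is a logical array on the shared grid and
#'   `density_override` (optional) a relative ED applied regardless of HU.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(structures) {
  dims <- NULL
  for (s in structures) {
    stopifnot(is.character(s$name), is.logical(s$mask))
    if (is.null(dims)) dims <- dim(s$mask)
    if (!all(dim(s$mask) == dims)) stop("structure masks must share dims")
    if (!is.null(s$density_override) && s$density_override < 0)
      stop("density override must be >= 0")
  }
  structure(list(structures = structures), class = "structure_set")
}

#' Convert a CT-number grid to relative electron density
#'
#' Piecewise-linear interpolation of the user-supplied CT-to-ED table with
#' end clamping; voxels inside a structure that carries a density override
#' take that ED regardless of CT number, mirroring how TPS density
#' overrides behave.
#'
#' @param ct [grid3d()] of CT numbers (HU).
#' @param table a [ct_to_ed_table()].
#' @param overrides optional [structure_set()]; structures with a
#'   `density_override` replace the converted ED inside their mask.
#' @param body_mask optional logical array for the patient outline.
#' @return a [density_volume()].
#' @examples
#' tab <- ct_to_ed_table(c(-1000, 0, 1000), c(0, 1, 2))
#' ct <- grid3d(500, spacing = 5, origin = c(0, 0, 0), dims = c(2, 2, 2))
#' hu_to_density(ct, tab)$grid$values[1]  # 1.5
#' @export
hu_to_density <- function(ct, table, overrides = NULL, body_mask = NULL) {
  stopifnot(inherits(ct, "grid3d"))
  if (!inherits(table, "ct_to_ed_table"))
    stop("`table` must be a ct_to_ed_table")
  ed <- stats::approx(table$hu, table$ed, xout = as.vector(ct$values),
                      rule = 2)$y
  ed <- array(ed, dim = dim(ct$values))
  if (!is.null(overrides)) {
    stopifnot(inherits(overrides, "structure_set"))
    for (s in overrides$structures) {
      if (!is.null(s$density_override)) {
        if (!all(dim(s$mask) == dim(ed)))
          stop("override mask dims do not match the CT grid")
        ed[s$mask] <- s$density_override
      }
    }
  }
  density_volume(grid3d(ed, ct$spacing, ct$origin), body_mask = body_mask)
}
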