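#' Collapsed-cone superposition of a TERMA grid
#'
#' Voxel-centric (collection) implementation: every dose voxel gathers
#' energy along each cone axis from upstream TERMA voxels, with the kernel
#' argument equal to the radiological (ED-scaled) distance along the cone
#' ray — this density scaling is what distinguishes superposition from
#' plain convolution. With `tilt = TRUE` the cone axes are rotated per
#' voxel so the kernel's forward axis follows the local ray from the
#' source. The kernel is chosen per voxel from the recorded TERMA mean
#' energy by linear blending of the two bracketing tabulated kernels,
#' realizing beam hardening in the superposition step as well.
#'
#' The result is in the same engine units as TERMA; absolute dose comes
#' from the beam output calibration in [calc_plan_dose()].
#'
#' @param terma a [compute_terma()] result.
#' @param density the [density_volume()] used for kernel density scaling
#'   (after any HCS filtering; TERMA always uses the raw density).
#' @param cck_family a [build_cck_family()] list (or a single
#'   [build_cck()] table).
#' @param tilt rotate cone axes per voxel toward the source.
#' @param step_mm ray-marching step; default the smallest voxel dimension.
#' @param mask logical array of dose voxels to compute (default: all).
#' @param contamination add the TERMA's electron-contamination surface
#'   channel to the dose.
#' @return a [grid3d()] of dose in engine units.
#' @export
superpose <- function(terma, density, cck_family, tilt = TRUE,
                      step_mm = NULL, mask = NULL, contamination = TRUE) {
  stopifnot(inherits(terma, "terma_grid"),
            inherits(density, "density_volume"))
  if (inherits(cck_family, "cck_table")) {
    cck_family <- list(cck_family)
    attr(cck_family, "energies") <- cck_family[[1]]$energy_mev %||% 1
  }
  g <- terma$grid
  if (!same_geometry(g, density$grid))
    stop("TERMA and density grids are misaligned")
  if (is.null(step_mm)) step_mm <- min(g$spacing)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(g$values))

  # per-voxel kernel: linear blend of the two tabulated energies
  # bracketing the recorded mean energy (clamped at the grid ends)
  energies <- attr(cck_family, "energies")
  me <- as.vector(terma$mean_energy$values)
  if (length(energies) > 1L) {
    lo <- pmin(pmax(findInterval(me, energies), 1L), length(energies) - 1L)
    kw <- pmin(pmax((me - energies[lo]) / (energies[lo + 1L] - energies[lo]),
                    0), 1)
  } else {
    lo <- rep(1L, length(me)); kw <- rep(0, length(me))
  }
  kidx <- lo - 1L

  cones <- cck_family[[1]]$cones
  n_cones <- nrow(cones$directions)
  edges <- cck_family[[1]]$radii_mm
  # stacked CK rows: kernel k, cone m -> row k * n_cones + m
  ck <- do.call(rbind, lapply(cck_family, function(t) t$CK))
  dr <- edges[2] - edges[1]

  dose <- cpp_superpose(g$values, density$grid$values, g$spacing, g$origin,
                        as.integer(kidx), as.numeric(kw), ck, n_cones, dr,
                        max(edges),
                        cones$directions, terma$geom$source, terma$geom$dir,
                        terma$geom$parallel, tilt, step_mm,
                        as.logical(mask))
  if (contamination) dose <- dose + terma$contamination$values
  grid3d(dose, g$spacing, g$origin)
}
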