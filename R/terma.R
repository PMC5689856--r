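#' Radiological (water-equivalent) path length between two points
#'
#' Exact Siddon-style voxel-traversal line integral of relative electron
#' density along the segment from `src` to `dst`, in mm water-equivalent.
#' Segments outside the grid contribute zero; a zero-length ray returns 0.
#'
#' @param density a [density_volume()].
#' @param src,dst mm positions (length 3).
#' @return water-equivalent path length, mm.
#' @examples
#' dv <- build_water_cube(100, spacing = 5)
#' radiological_path(dv, c(0, 0, 200), c(0, 0, 0))  # 50 mm of water
#' @export
radiological_path <- function(density, src, dst) {
  stopifnot(inherits(density, "density_volume"))
  g <- density$grid
  cpp_radiological_path(g$values, g$spacing, g$origin,
                        as.numeric(src), as.numeric(dst))
}

#' Compute polyenergetic TERMA from a fluence map
#'
#' Casts one ray per fluence pixel from the source through the density
#' volume. For every voxel the ray crosses and every spectrum bin, the
#' energy released is `fluence_bin * (mu/rho)_material(ED) * E_bin *
#' exp(-(mu/rho)_water * d_we) * (SAD/r)^2`, where `d_we` is the
#' water-equivalent (ED-scaled) depth along the heterogeneity-corrected
#' ray path. Bin-wise attenuation of the 16-bin spectrum is the beam
#' hardening mechanism; the TERMA-weighted mean photon energy is recorded
#' per voxel for hardening-aware kernel selection downstream. Attenuation
#' uses water coefficients with ED-scaled path (effective pathlength);
#' the local material coefficients enter only the energy-release factor.
#'
#' TERMA is in engine units per MU until the beam output calibration is
#' applied at the dose stage.
#'
#' @param fluence a [compute_fluence()] map.
#' @param density a [density_volume()].
#' @param inv_sq apply inverse-square divergence (ignored for parallel
#'   beams).
#' @param mu_mm_override optional 16-vector replacing the water attenuation
#'   per mm (analytic tests).
#' @param release_uniform if `TRUE`, the material release factor is set to
#'   1 so TERMA reduces to pure attenuated fluence times energy.
#' @return object of class `terma_grid`: `grid` (TERMA), `mean_energy`
#'   (MeV), `contamination` (surface-channel deposit), and bookkeeping
#'   attributes.
#' @export
compute_terma <- function(fluence, density, inv_sq = TRUE,
                          mu_mm_override = NULL, release_uniform = FALSE) {
  stopifnot(inherits(fluence, "fluence_map"),
            inherits(density, "density_volume"))
  g <- density$grid
  geom <- fluence$geom
  nx <- length(fluence$x); ny <- length(fluence$y)
  px <- rep(fluence$x, times = ny); py <- rep(fluence$y, each = nx)
  rays <- cbind(px * geom$ex[1] + py * geom$ey[1],
                px * geom$ex[2] + py * geom$ey[2],
                px * geom$ex[3] + py * geom$ey[3])

  eb <- fluence$spectrum$bin_energies
  mu_mm <- if (!is.null(mu_mm_override)) mu_mm_override else
    material_blend(1.0)$mu_over_rho / 10   # water, 1 g/cm^3, per mm
  ed_lut_max <- max(4, max(g$values))
  if (release_uniform) {
    rel <- matrix(1, nrow = 2, ncol = 16)
  } else {
    ed_lut <- seq(0, ed_lut_max, length.out = 401L)
    rel <- material_blend(ed_lut)$mu_over_rho
  }

  res <- cpp_terma_raycast(
    g$values, g$spacing, g$origin, rays,
    as.numeric(fluence$primary), as.numeric(fluence$extrafocal),
    as.numeric(fluence$contamination),
    fluence$spectrum$bin_weights, fluence$extrafocal_spectrum$bin_weights,
    eb, mu_mm, rel, ed_lut_max,
    geom$source, geom$parallel, geom$dir, geom$sad, inv_sq,
    attr(fluence, "contam_tau") %||% 12)

  # dose-units conversion for the contamination channel: the mean
  # TERMA-per-unit-fluence factor in water
  kappa <- sum(fluence$spectrum$bin_weights *
                 (if (release_uniform) 1 else material_blend(1.0)$mu_over_rho) *
                 eb)
  structure(list(grid = grid3d(res$terma, g$spacing, g$origin),
                 mean_energy = grid3d(pmax(res$mean_energy, 0) + 0,
                                      g$spacing, g$origin),
                 contamination = grid3d(res$contamination * kappa,
                                        g$spacing, g$origin),
                 geom = geom, mu = fluence$mu),
            class = "terma_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.terma_grid <- function(x, ...) {
  cat("<terma_grid>\n"); print(x$grid)
  invisible(x)
}

#' Per-angle TERMA grids for an arc plan
#'
#' Evaluates TERMA at the center of every 2 degree (by default) angular
#' sector of the arc, with sector MU taken from the control points. Static
#' plans degenerate to one TERMA per beam.
#'
#' @param plan an arc plan from [build_arc_plan()] (or a static plan).
#' @param density a [density_volume()].
#' @param beam a [beam_model()].
#' @param terma_deg angular TERMA resolution, degrees.
#' @param fluence_spacing,plane_margin fluence plane discretization, mm.
#' @return list of entries `list(gantry_deg, mu, terma)`.
#' @export
terma_for_arc <- function(plan, density, beam, terma_deg = 2,
                          fluence_spacing = 2, plane_margin = 30) {
  stopifnot(inherits(plan, "ccd_plan"))
  segs <- arc_sectors(plan, terma_deg)
  lapply(segs, function(s) {
    fl <- compute_fluence(beam, plan_aperture(s), s$mu, s$gantry_deg,
                          plane_spacing = fluence_spacing,
                          plane_margin = plane_margin)
    list(gantry_deg = s$gantry_deg, mu = s$mu,
         terma = compute_terma(fl, density))
  })
}

# resample an arc plan into sectors of `deg` at sector centers; static
# plans pass through unchanged
arc_sectors <- function(plan, deg) {
  if (plan$type != "arc") return(plan$beams)
  cps <- plan$beams
  ang <- vapply(cps, function(b) b$gantry_deg, 0)
  mu_cum <- cumsum(vapply(cps, function(b) b$mu, 0))
  span <- range(ang)
  n_sec <- as.integer(round((span[2] - span[1]) / deg))
  edges <- seq(span[1], span[2], length.out = n_sec + 1L)
  lapply(seq_len(n_sec), function(i) {
    a0 <- edges[i]; a1 <- edges[i + 1L]
    mu <- stats::approx(ang, mu_cum, xout = a1)$y -
      stats::approx(ang, mu_cum, xout = a0)$y
    ctr <- (a0 + a1) / 2
    # aperture of the nearest control point
    j <- which.min(abs(ang - ctr))
    s <- cps[[j]]
    s$gantry_deg <- ctr %% 360
    s$mu <- mu
    s
  })
}
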