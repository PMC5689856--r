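#' Engine configuration
#'
#' Collects the discretization knobs of the full calculation chain. The
#' defaults match the intended clinical-like operating point (1 mm fluence
#' plane, 8 x 6 collapsed cones, 60 mm kernel reach, tilting on, arc TERMA
#' every 2 degrees grouped into 5 degree superpositions); tests use coarser
#' settings for speed.
#'
#' @param fluence_spacing fluence pixel size at isocenter, mm.
#' @param plane_margin fluence plane margin beyond the jaws, mm.
#' @param n_zenith,n_azimuth collapsed-cone discretization.
#' @param kernel_energies tabulated kernel energies (MeV) for the
#'   hardening-aware kernel lookup.
#' @param r_max_mm kernel reach, mm.
#' @param step_mm superposition ray-marching step (default: voxel size).
#' @param tilt per-voxel kernel tilting.
#' @param inv_sq inverse-square divergence in TERMA.
#' @param contamination include the electron-contamination surface term.
#' @param hcs `NULL` (off, the default) or an [hcs_params()] object.
#' @param arc_terma_deg,arc_super_deg angular resolutions for arcs.
#' @return a list of class `engine_config`.
#' @export
engine_config <- function(fluence_spacing = 1, plane_margin = 40,
                          n_zenith = 8, n_azimuth = 6,
                          kernel_energies = c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 8),
                          r_max_mm = 60, step_mm = NULL, tilt = TRUE,
                          inv_sq = TRUE, contamination = TRUE, hcs = NULL,
                          arc_terma_deg = 2, arc_super_deg = 5) {
  cfg <- list(fluence_spacing = fluence_spacing, plane_margin = plane_margin,
              n_zenith = n_zenith, n_azimuth = n_azimuth,
              kernel_energies = kernel_energies, r_max_mm = r_max_mm,
              step_mm = step_mm, tilt = tilt, inv_sq = inv_sq,
              contamination = contamination, hcs = hcs,
              arc_terma_deg = arc_terma_deg, arc_super_deg = arc_super_deg)
  class(cfg) <- "engine_config"
  cfg
}

# cones + CCK family are pure functions of the config; memoized per call
# chain via the config object
engine_kernels <- function(cfg) {
  key <- paste(cfg$n_zenith, cfg$n_azimuth, cfg$r_max_mm,
               paste(cfg$kernel_energies, collapse = ","))
  cache <- get0("kernel_cache", envir = .ccdose_env)
  if (!is.null(cache) && identical(cache$key, key)) return(cache$fam)
  fam <- build_cck_family(cfg$kernel_energies,
                          cone_set(cfg$n_zenith, cfg$n_azimuth),
                          cfg$r_max_mm)
  assign("kernel_cache", list(key = key, fam = fam), envir = .ccdose_env)
  fam
}

#' Dose of a single static segment, in engine units per its MU
#'
#' Runs the three calculation steps — fluence, TERMA, superposition — for
#' one aperture at one gantry angle. Absolute scaling is applied by the
#' caller ([calc_plan_dose()]) from the beam calibration.
#'
#' @param beam a [beam_model()].
#' @param ap an [aperture()].
#' @param mu segment monitor units.
#' @param gantry_deg gantry angle.
#' @param density a [density_volume()].
#' @param cfg an [engine_config()].
#' @param mask optional logical array restricting computed dose voxels.
#' @param sad override SAD (`Inf` = parallel beam for analytic tests).
#' @return a [grid3d()] of dose in engine units.
#' @export
calc_segment_dose <- function(beam, ap, mu, gantry_deg, density,
                              cfg = engine_config(), mask = NULL,
                              sad = beam$sad) {
  fl <- compute_fluence(beam, ap, mu, gantry_deg,
                        plane_spacing = cfg$fluence_spacing,
                        plane_margin = cfg$plane_margin, sad = sad)
  attr(fl, "contam_tau") <- beam$contamination$depth_constant
  tm <- compute_terma(fl, density, inv_sq = cfg$inv_sq)
  sup_density <- density
  if (!is.null(cfg$hcs))
    sup_density <- apply_hcs(density, fl$geom$dir, cfg$hcs)
  superpose(tm, sup_density, engine_kernels(cfg), tilt = cfg$tilt,
            step_mm = cfg$step_mm, mask = mask,
            contamination = cfg$contamination)
}

#' Calibrate absolute output per monitor unit
#'
#' Runs the engine once under the reference conditions stored in the beam
#' calibration block (a jaw-defined `ref_field_cm` square field on the
#' water phantom, dose point at `ref_depth_mm` on the central axis with the
#' surface at `ref_ssd_mm`) and sets the output scale so the computed dose
#' at the reference point equals `dose_per_mu`. Calibrating an already
#' calibrated model is idempotent (the incremental scale is 1).
#'
#' @param beam a [beam_model()].
#' @param water_phantom optional [density_volume()]; default a 200 mm
#'   water cube whose surface sits at the reference SSD.
#' @param cfg an [engine_config()].
#' @return the beam with `output_scale` set; the incremental scale factor
#'   is in attribute `"scale_factor"`.
#' @export
calibrate_output <- function(beam, water_phantom = NULL,
                             cfg = engine_config()) {
  cal <- beam$calibration
  if (is.null(water_phantom))
    water_phantom <- build_water_cube(200, spacing = 2.5)
  # the default phantom places its surface at z = +100 (SSD 900 for
  # SAD 1000); the reference depth then lands at z = 100 - ref_depth_mm
  ref_point <- c(0, 0, 100 - cal$ref_depth_mm)
  h <- cal$ref_field_cm * 10 / 2
  ap <- aperture(c(-h, h), c(-h, h))
  g <- water_phantom$grid
  centers <- expand.grid(x = grid_axis(g, 1), y = grid_axis(g, 2),
                         z = grid_axis(g, 3))
  d2 <- (centers$x - ref_point[1])^2 + (centers$y - ref_point[2])^2 +
    (centers$z - ref_point[3])^2
  mask <- array(d2 <= max(6, min(g$spacing))^2, dim = dim(g$values))
  if (!any(mask)) mask[which.min(d2)] <- TRUE
  dose <- calc_segment_dose(beam, ap, mu = 1, gantry_deg = 0,
                            density = water_phantom, cfg = cfg, mask = mask)
  prev <- if (is.na(beam$output_scale)) 1 else beam$output_scale
  d_ref <- grid_sample(dose, ref_point, rule = "clamp") * prev
  if (!is.finite(d_ref) || d_ref <= 0)
    stop("calibration failed: zero computed dose at the reference point")
  scale <- cal$dose_per_mu / d_ref
  beam$output_scale <- prev * scale
  attr(beam, "scale_factor") <- scale
  beam
}

#' Absolute plan dose
#'
#' Static plans: per-segment fluence, TERMA and superposition, summed
#' (each segment already carries its MU). Arcs: TERMA is evaluated every
#' `arc_terma_deg` (2 degrees), accumulated into `arc_super_deg`
#' (5 degree) groups, and each group is superposed once — high TERMA but
#' low superposition angular resolution. The result is scaled to absolute
#' Gy by the beam output calibration.
#'
#' @param plan a plan from the [plans] builders.
#' @param density a [density_volume()].
#' @param beam a calibrated [beam_model()] (see [calibrate_output()]).
#' @param cfg an [engine_config()].
#' @param mask optional logical array restricting computed dose voxels.
#' @return a [grid3d()] of dose in Gy, with attributes `n_terma_evals`,
#'   `n_superpositions` and `mu_delivered`.
#' @export
calc_plan_dose <- function(plan, density, beam, cfg = engine_config(),
                           mask = NULL) {
  stopifnot(inherits(plan, "ccd_plan"))
  if (is.na(beam$output_scale))
    stop("beam model is uncalibrated; run calibrate_output() first")
  g <- density$grid
  zero <- grid3d(0, g$spacing, g$origin, dims = dim(g$values))
  if (length(plan$beams) == 0L) {
    warning("empty plan: returning a zero dose grid")
    attr(zero, "n_terma_evals") <- 0L
    attr(zero, "n_superpositions") <- 0L
    attr(zero, "mu_delivered") <- 0
    return(zero)
  }

  total <- zero$values
  n_terma <- 0L; n_super <- 0L; mu_sum <- 0

  if (plan$type != "arc") {
    for (b in plan$beams) {
      d <- calc_segment_dose(beam, plan_aperture(b), b$mu, b$gantry_deg,
                             density, cfg, mask = mask)
      total <- total + d$values
      n_terma <- n_terma + 1L; n_super <- n_super + 1L
      mu_sum <- mu_sum + b$mu
    }
  } else {
    sectors <- arc_sectors(plan, cfg$arc_terma_deg)
    group_of <- function(ang) as.integer(1 + (ang %% 360) %/% cfg$arc_super_deg)
    groups <- vapply(sectors, function(s) group_of(s$gantry_deg), 1L)
    for (grp in sort(unique(groups))) {
      sel <- sectors[groups == grp]
      acc <- NULL
      for (s in sel) {
        fl <- compute_fluence(beam, plan_aperture(s), s$mu, s$gantry_deg,
                              plane_spacing = cfg$fluence_spacing,
                              plane_margin = cfg$plane_margin)
        attr(fl, "contam_tau") <- beam$contamination$depth_constant
        tm <- compute_terma(fl, density, inv_sq = cfg$inv_sq)
        n_terma <- n_terma + 1L
        mu_sum <- mu_sum + s$mu
        if (is.null(acc)) {
          acc <- tm
          acc$energy_wsum <- tm$mean_energy$values * tm$grid$values
        } else {
          acc$grid$values <- acc$grid$values + tm$grid$values
          acc$contamination$values <- acc$contamination$values +
            tm$contamination$values
          acc$energy_wsum <- acc$energy_wsum +
            tm$mean_energy$values * tm$grid$values
        }
      }
      acc$mean_energy$values <- ifelse(acc$grid$values > 0,
                                       acc$energy_wsum / acc$grid$values, 0)
      # the group's superposition geometry uses its central angle
      ctr_ang <- mean(vapply(sel, function(s) s$gantry_deg, 0))
      acc$geom <- beam_geometry(ctr_ang, beam$sad)
      sup_density <- density
      if (!is.null(cfg$hcs))
        sup_density <- apply_hcs(density, acc$geom$dir, cfg$hcs)
      d <- superpose(acc, sup_density, engine_kernels(cfg), tilt = cfg$tilt,
                     step_mm = cfg$step_mm, mask = mask,
                     contamination = cfg$contamination)
      total <- total + d$values
      n_super <- n_super + 1L
    }
  }
  out <- grid3d(total * beam$output_scale, g$spacing, g$origin)
  attr(out, "n_terma_evals") <- n_terma
  attr(out, "n_superpositions") <- n_super
  attr(out, "mu_delivered") <- mu_sum
  out
}
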