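#' Linac beam model
#'
#' Bundles the treatment-head description the engine needs: primary and
#' extrafocal spectra and radial intensity profiles, the electron
#' contamination term, collimator physics constants, machine geometry, and
#' the absolute calibration block. Defaults are surrogate values per nominal
#' beam quality; vendor beam data are commissioning measurements and are
#' not published.
#'
#' The extrafocal (head-scatter) source is a finite Gaussian source below
#' the target: its fluence is the aperture-masked primary convolved with
#' the projected source width, so it spills beyond the geometric field edge
#' and is partially occluded for small apertures. Electron contamination is
#' a field-size-dependent surface term with exponential depth falloff.
#'
#' @param energy_label `"6MV"`, `"10FFF"` or `"15MV"`.
#' @param dose_per_mu absolute calibration: Gy per MU at reference
#'   conditions (10 x 10 cm^2 field, `ref_depth_mm` deep on the water
#'   phantom at `ref_ssd_mm`).
#' @param ... overrides for any model field (see Details in the source).
#' @return object of class `beam_model`.
#' @examples
#' bm <- beam_model("6MV")
#' bm$sad
#' @export
beam_model <- function(energy_label = c("6MV", "10FFF", "15MV"),
                       dose_per_mu = 0.01, ...) {
  energy_label <- match.arg(energy_label)
  r <- seq(0, 250, by = 10)
  radial <- switch(energy_label,
    # flattened beams: slight off-axis horns; FFF: forward-peaked falloff
    "6MV"   = 1 + 0.020 * (r / 100)^2 - 0.00015 * pmax(r - 150, 0)^1.2,
    "15MV"  = 1 + 0.012 * (r / 100)^2 - 0.00015 * pmax(r - 150, 0)^1.2,
    "10FFF" = exp(-0.5 * (r / 160)^2))
  contamination <- switch(energy_label,
    "6MV"   = list(amplitude = 0.05, depth_constant = 10, sigma_iso = 30),
    "10FFF" = list(amplitude = 0.08, depth_constant = 12, sigma_iso = 30),
    "15MV"  = list(amplitude = 0.07, depth_constant = 18, sigma_iso = 30))
  model <- list(
    energy_label = energy_label,
    primary_spectrum = surrogate_spectrum(energy_label),
    extrafocal_spectrum = surrogate_extrafocal_spectrum(energy_label),
    primary_radial_profile = list(r_mm = r, intensity = pmax(radial, 0.05)),
    extrafocal_fraction = 0.08,
    extrafocal_sigma_iso = 20,       # projected source width at isocenter, mm
    contamination = contamination,
    sad = 1000,
    calibration = list(dose_per_mu = dose_per_mu, ref_field_cm = 10,
                       ref_depth_mm = 100, ref_ssd_mm = 900),
    mlc = list(leaf_widths = rep(5, 40), transmission = 0.016,
               leaf_end_radius = 80, leaf_thickness = 60,
               tongue_groove_width = 1.0),
    jaw_transmission = 0.002,
    output_scale = NA_real_)
  model <- utils::modifyList(model, list(...))
  stopifnot(model$sad > 0,
            model$extrafocal_fraction >= 0, model$extrafocal_fraction <= 1,
            model$jaw_transmission >= 0, model$jaw_transmission <= 1)
  class(model) <- "beam_model"
  model
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<beam_model> %s  SAD %g mm  dose/MU %g Gy @ %g mm depth\n",
    "  mean primary energy %.2f MeV, extrafocal fraction %.2f, %s\n"),
    x$energy_label, x$sad, x$calibration$dose_per_mu,
    x$calibration$ref_depth_mm,
    spectrum_mean_energy(x$primary_spectrum), x$extrafocal_fraction,
    if (is.na(x$output_scale)) "uncalibrated" else
      sprintf("output scale %.4g", x$output_scale)))
  invisible(x)
}

#' Read/write a beam model configuration file (YAML)
#'
#' Human-readable key/value representation with nested sections; spectra
#' are stored as 16 weights on the engine energy bins.
#'
#' @param model a [beam_model()].
#' @param path file path.
#' @return `read_beam_model` returns a [beam_model()].
#' @export
write_beam_model <- function(model, path) {
  x <- unclass(model)
  x$primary_spectrum <- list(bin_weights = model$primary_spectrum$bin_weights)
  x$extrafocal_spectrum <- list(bin_weights = model$extrafocal_spectrum$bin_weights)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' @rdname write_beam_model
#' @export
read_beam_model <- function(path) {
  x <- yaml::read_yaml(path)
  m <- beam_model(x$energy_label)
  x$primary_spectrum <- spectrum(unlist(x$primary_spectrum$bin_weights))
  x$extrafocal_spectrum <- spectrum(unlist(x$extrafocal_spectrum$bin_weights))
  x$primary_radial_profile <- lapply(x$primary_radial_profile, unlist)
  m <- utils::modifyList(unclass(m), x)
  class(m) <- "beam_model"
  m
}

#' Beam geometry for a gantry angle
#'
#' IEC-style coplanar geometry: at gantry 0 the source sits above the
#' isocenter at `(0, 0, sad)` and the beam points down `-z`; the gantry
#' rotates about the y (superior-inferior) axis. The fluence-plane axes
#' `ex` (crossplane, leaf travel) and `ey` (inplane) span the isocenter
#' plane.
#'
#' @param gantry_deg gantry angle in degrees.
#' @param sad source-axis distance, mm; `Inf` gives a parallel
#'   (non-divergent) beam used by analytic tests.
#' @return list with `source`, `dir`, `ex`, `ey`, `parallel`.
#' @export
beam_geometry <- function(gantry_deg, sad = 1000) {
  g <- gantry_deg * pi / 180
  dir <- -c(sin(g), 0, cos(g))
  list(source = if (is.finite(sad)) c(sin(g), 0, cos(g)) * sad else -dir * 1e7,
       dir = dir,
       ex = c(cos(g), 0, -sin(g)),
       ey = c(0, 1, 0),
       parallel = !is.finite(sad),
       sad = sad)
}
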