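#' Synthetic phantoms
#'
#' Deterministic phantom builders covering the validation geometries:
#' a homogeneous water cube, a wide water/lung/water slab stack, and an
#' anthropomorphic-style thorax with two low-density lung cylinders and an
#' optional spherical unit-density target. All phantoms use the isocenter-
#' at-origin frame; the slab and cube place their entry surface at
#' z = +100 mm so that a gantry-0 beam at SAD 1000 mm gives SSD 900 mm.
#'
#' @name phantoms
NULL

#' @describeIn phantoms Homogeneous water cube (default 20 cm side), ED 1.0.
#' @param side_mm cube side, mm.
#' @param spacing voxel spacing, mm (scalar or triple).
#' @return a [density_volume()].
#' @export
build_water_cube <- function(side_mm = 200, spacing = 2.5) {
  if (side_mm <= 0) stop("`side_mm` must be > 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  n <- pmax(1L, as.integer(round(side_mm / spacing)))
  lo <- c(-side_mm / 2, -side_mm / 2, 100 - side_mm)
  g <- grid3d(1.0, spacing, origin = lo + spacing / 2, dims = n)
  density_volume(g, body_mask = array(TRUE, dim = n))
}

#' @describeIn phantoms Wide slab phantom: 50 mm water, 50 mm lung
#'   (ED 0.3), 200 mm water along the beam (z) axis; 300 mm lateral extent.
#'   Entry surface at z = +100 mm, so geometric depth is `100 - z`.
#' @param lung_ed electron density of the lung slab.
#' @export
build_slab_phantom <- function(spacing = 2.5, lung_ed = 0.3) {
  if (any(spacing <= 0)) stop("`spacing` must be > 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  n <- pmax(1L, as.integer(round(c(300, 300, 300) / spacing)))
  origin <- c(-150, -150, -200) + spacing / 2
  z <- origin[3] + (seq_len(n[3]) - 1) * spacing[3]
  depth <- 100 - z
  ed_z <- ifelse(depth < 50, 1.0, ifelse(depth < 100, lung_ed, 1.0))
  vals <- array(rep(ed_z, each = n[1] * n[2]), dim = n)
  density_volume(grid3d(vals, spacing, origin),
                 body_mask = array(TRUE, dim = n))
}

#' @describeIn phantoms Thorax phantom: elliptical-cross-section body
#'   (300 x 200 mm in x-z, 300 mm long in y, ED 1.0) with two lung
#'   cylinders (ED 0.21) along y and an optional 40 mm diameter unit-density
#'   spherical target centered in the right lung. With `with_target = TRUE`
#'   the grid is centered on the target (the isocenter sits at the target
#'   center, as in target-centered setups); otherwise on the body.
#' @param with_target include the spherical target and center on it.
#' @return `build_thorax_phantom` returns
#'   `list(density = density_volume, structures = structure_set)`.
#' @export
build_thorax_phantom <- function(spacing = 2.5, with_target = TRUE) {
  if (any(spacing <= 0)) stop("`spacing` must be > 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  lung_r <- 55; lung_cx <- 75; lung_len <- 240; target_r <- 20
  body_c <- if (with_target) c(-lung_cx, 0, 0) else c(0, 0, 0)
  pad <- 10
  lo <- body_c - c(150, 150, 100) - pad
  hi <- body_c + c(150, 150, 100) + pad
  n <- pmax(1L, as.integer(round((hi - lo) / spacing)))
  origin <- lo + spacing / 2
  xs <- origin[1] + (seq_len(n[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(n[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(n[3]) - 1) * spacing[3]
  X <- array(xs, dim = n)
  Y <- array(rep(ys, each = n[1]), dim = n)
  Z <- array(rep(zs, each = n[1] * n[2]), dim = n)

  body <- ((X - body_c[1]) / 150)^2 + ((Z - body_c[3]) / 100)^2 <= 1 &
    abs(Y - body_c[2]) <= 150
  in_y <- abs(Y - body_c[2]) <= lung_len / 2
  lung_r_mask <- (X - (body_c[1] + lung_cx))^2 + (Z - body_c[3])^2 <= lung_r^2 & in_y
  lung_l_mask <- (X - (body_c[1] - lung_cx))^2 + (Z - body_c[3])^2 <= lung_r^2 & in_y
  lungs <- (lung_r_mask | lung_l_mask) & body

  ed <- array(0, dim = n)
  ed[body] <- 1.0
  ed[lungs] <- 0.21
  structures <- list(list(name = "body", mask = body),
                     list(name = "lungs", mask = lungs))
  if (with_target) {
    tc <- body_c + c(lung_cx, 0, 0)   # == origin of the frame
    target <- (X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2 <= target_r^2
    ed[target] <- 1.0
    structures <- c(structures,
                    list(list(name = "target", mask = target,
                              density_override = 1.0)))
  }
  list(density = density_volume(grid3d(ed, spacing, origin),
                                body_mask = body),
       structures = structure_set(structures))
}

#' Treatment plans
#'
#' Plans are lists of static segments or arc control points in a JSON-
#' serializable dialect mirroring DICOM RT Plan semantics: gantry angles in
#' IEC degrees, jaw/MLC positions in mm at isocenter, MU per segment or per
#' control point.
#'
#' @name plans
NULL

new_plan <- function(type, beams, energy_label, total_mu) {
  structure(list(type = type, beams = beams, energy_label = energy_label,
                 total_mu = total_mu), class = "ccd_plan")
}

#' @export
print.ccd_plan <- function(x, ...) {
  cat(sprintf("<ccd_plan> %s, %s, %d %s, %g MU total\n", x$type,
              x$energy_label, length(x$beams),
              if (x$type == "arc") "control points" else "beams", x$total_mu))
  invisible(x)
}

#' @describeIn plans Single static open square field (optionally with an
#'   MLC-defined square aperture inside the jaw opening), gantry 0.
#' @param side_cm field side at isocenter, cm (jaw-defined).
#' @param energy_label beam quality label.
#' @param mu monitor units.
#' @param mlc_side_cm if given, the MLC defines a `mlc_side_cm` square
#'   aperture centered in the jaw opening.
#' @export
build_square_field_plan <- function(side_cm, energy_label = "6MV", mu = 100,
                                    mlc_side_cm = NULL) {
  if (side_cm <= 0) stop("`side_cm` must be > 0")
  h <- side_cm * 10 / 2
  leaf_pairs <- NULL
  if (!is.null(mlc_side_cm)) {
    hm <- mlc_side_cm * 10 / 2
    widths <- rep(5, 40)
    edges <- c(0, cumsum(widths)) - sum(widths) / 2
    ctr <- (edges[-1] + edges[-length(edges)]) / 2
    open <- abs(ctr) < hm
    leaf_pairs <- cbind(ifelse(open, -hm, 0), ifelse(open, hm, 0))
  }
  beams <- list(list(gantry_deg = 0, jaw_x = c(-h, h), jaw_y = c(-h, h),
                     leaf_pairs = leaf_pairs, mu = mu))
  new_plan("static", beams, energy_label, mu)
}

#' @describeIn plans Five equally weighted coplanar beams at equispaced
#'   gantry angles, each MLC aperture a disk covering the 40 mm spherical
#'   target expanded by a 7 mm margin (27 mm radius at isocenter).
#' @param margin_mm aperture margin around the 20 mm target radius.
#' @param total_mu total plan MU, split evenly.
#' @export
build_five_beam_lung_plan <- function(energy_label = "6MV", total_mu = 250,
                                      margin_mm = 7) {
  r_ap <- 20 + margin_mm
  widths <- rep(5, 40)
  edges <- c(0, cumsum(widths)) - sum(widths) / 2
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  half <- ifelse(abs(ctr) < r_ap, sqrt(pmax(r_ap^2 - ctr^2, 0)), 0)
  leaf_pairs <- unname(cbind(-half, half))
  jaw <- c(-r_ap - 5, r_ap + 5)
  beams <- lapply(seq(0, 288, by = 72), function(g)
    list(gantry_deg = g, jaw_x = jaw, jaw_y = jaw,
         leaf_pairs = leaf_pairs, mu = total_mu / 5))
  new_plan("static", beams, energy_label, total_mu)
}

#' @describeIn plans Full 360 degree arc with control points every
#'   `cp_spacing_deg` (both endpoints included, so 181 control points at the
#'   2 degree default). The first control point carries no MU; each later
#'   one carries the MU of the sector ending at it.
#' @param cp_spacing_deg control-point spacing; must divide 360.
#' @param side_cm aperture side (jaw square) for every control point.
#' @export
build_arc_plan <- function(cp_spacing_deg = 2, energy_label = "6MV",
                           total_mu = 200, side_cm = 10) {
  if (cp_spacing_deg <= 0 || 360 %% cp_spacing_deg != 0)
    stop("`cp_spacing_deg` must divide 360")
  angles <- seq(0, 360, by = cp_spacing_deg)
  n_seg <- length(angles) - 1L
  h <- side_cm * 10 / 2
  cps <- lapply(seq_along(angles), function(i)
    list(gantry_deg = angles[i], jaw_x = c(-h, h), jaw_y = c(-h, h),
         leaf_pairs = NULL, mu = if (i == 1L) 0 else total_mu / n_seg))
  new_plan("arc", cps, energy_label, total_mu)
}

#' Read/write a plan as JSON
#'
#' @param plan a plan from one of the [plans] builders.
#' @param path file path.
#' @return `read_plan` returns the plan object.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = TRUE)
  x$beams <- lapply(x$beams, function(b) {
    b$jaw_x <- unlist(b$jaw_x); b$jaw_y <- unlist(b$jaw_y)
    if (!is.null(b$leaf_pairs) && !is.matrix(b$leaf_pairs))
      b$leaf_pairs <- matrix(unlist(b$leaf_pairs), ncol = 2, byrow = TRUE)
    b
  })
  structure(x, class = "ccd_plan")
}

plan_aperture <- function(beam_entry) {
  aperture(beam_entry$jaw_x, beam_entry$jaw_y,
           leaf_pairs = beam_entry$leaf_pairs)
}
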