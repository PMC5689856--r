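#' Heterogeneity-compensated superposition (HCS) parameters
#'
#' HCS is a deliberately nonphysical pre-filter: before superposition (and
#' only there — TERMA always sees the raw density), the density near
#' material interfaces is modified in a position- and direction-sensitive
#' way to compensate the known superposition bias at low-density
#' interfaces. The vendor filter is unpublished; this package implements a
#' parameterized one-sided exponential blend with the same stated
#' character. It is off by default.
#'
#' @param window_mm filter extent downstream of an interface, mm.
#' @param strength blending strength in `[0, 1]`; 0 is the identity.
#' @param interface_threshold ED step that qualifies as an interface.
#' @return object of class `hcs_params`.
#' @export
hcs_params <- function(window_mm = 10, strength = 0.5,
                       interface_threshold = 0.25) {
  stopifnot(window_mm >= 0, strength >= 0, strength <= 1,
            interface_threshold > 0)
  structure(list(window_mm = window_mm, strength = strength,
                 interface_threshold = interface_threshold),
            class = "hcs_params")
}

#' Apply the HCS density filter along a beam direction
#'
#' Along lines parallel to the beam direction, ED steps of at least
#' `interface_threshold` are detected and the density within `window_mm`
#' downstream of each interface is blended one-sidedly toward the upstream
#' flank value with weight `strength * exp(-3 s / window_mm)` at distance
#' `s` from the interface. Voxels farther than the window from every
#' qualifying interface are returned bit-exact; `strength = 0` is the
#' identity. The filtered volume stays within the range of the two flank
#' densities. Filtering is applied along the grid axis closest to the beam
#' direction (the phantom geometries of interest are axis-dominant).
#'
#' @param density a [density_volume()].
#' @param beam_direction unit vector of beam travel.
#' @param params an [hcs_params()].
#' @return a filtered [density_volume()] for use by superposition only.
#' @export
apply_hcs <- function(density, beam_direction, params = hcs_params()) {
  stopifnot(inherits(density, "density_volume"),
            inherits(params, "hcs_params"))
  if (params$strength == 0 || params$window_mm == 0) return(density)
  axis <- which.max(abs(beam_direction))
  downstream <- beam_direction[axis] > 0

  v <- density$grid$values
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(v, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  if (!downstream) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]

  h <- density$grid$spacing[axis]
  n <- nrow(m)
  J <- ceiling(params$window_mm / h)
  orig <- m
  steps <- abs(orig[-1, , drop = FALSE] - orig[-n, , drop = FALSE])
  for (i in seq_len(n - 1L)) {
    cols <- which(steps[i, ] >= params$interface_threshold)
    if (!length(cols)) next
    up <- orig[i, cols]                       # upstream flank value
    for (j in seq_len(J)) {
      if (i + j > n) break
      s <- (j - 0.5) * h                      # distance from the interface
      if (s > params$window_mm) break
      w <- params$strength * exp(-3 * s / params$window_mm)
      m[i + j, cols] <- (1 - w) * m[i + j, cols] + w * up
    }
  }
  if (!downstream) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  out <- aperm(array(m, dm), order(perm))
  density_volume(grid3d(out, density$grid$spacing, density$grid$origin),
                 body_mask = density$body_mask)
}
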