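#' Beam aperture: jaw positions and MLC leaf tips
#'
#' All positions are projected to the isocenter plane, in mm. Leaf rows run
#' along y (leaf travel along x); row i spans
#' `[leaf_edges[i], leaf_edges[i+1]]` in y. With `leaf_pairs = NULL` the MLC
#' is fully retracted.
#'
#' @param jaw_x,jaw_y length-2 `(lo, hi)` jaw positions, mm at isocenter.
#' @param leaf_pairs `n x 2` matrix of `(left_tip, right_tip)` per row, or
#'   `NULL` for retracted MLC.
#' @param leaf_widths per-row widths in mm (recycled); rows are centered on
#'   y = 0.
#' @return object of class `aperture`.
#' @export
aperture <- function(jaw_x, jaw_y, leaf_pairs = NULL, leaf_widths = 5) {
  jaw_x <- as.numeric(jaw_x); jaw_y <- as.numeric(jaw_y)
  stopifnot(length(jaw_x) == 2L, length(jaw_y) == 2L,
            jaw_x[1] <= jaw_x[2], jaw_y[1] <= jaw_y[2])
  leaf_edges <- NULL
  if (!is.null(leaf_pairs)) {
    leaf_pairs <- as.matrix(leaf_pairs)
    stopifnot(ncol(leaf_pairs) == 2L, all(leaf_pairs[, 1] <= leaf_pairs[, 2]))
    w <- rep_len(leaf_widths, nrow(leaf_pairs))
    leaf_edges <- c(0, cumsum(w)) - sum(w) / 2
  }
  structure(list(jaw_x = jaw_x, jaw_y = jaw_y, leaf_pairs = leaf_pairs,
                 leaf_edges = leaf_edges),
            class = "aperture")
}

#' Combined jaw + MLC transmission at points in the isocenter plane
#'
#' Open beam returns 1; points under a jaw are attenuated by
#' `jaw_transmission`, points under a leaf body by `mlc$transmission`.
#' Across a rounded leaf end the transmission follows the chord length of
#' the ray through a circle of radius `mlc$leaf_end_radius` relative to the
#' physical leaf thickness, giving the characteristic few-mm soft edge.
#' Within `mlc$tongue_groove_width` of an inter-leaf boundary the more
#' closed of the two adjacent rows governs (tongue-and-groove shadow).
#'
#' @param points n x 2 matrix (or length-2 vector) of (x, y) mm at isocenter.
#' @param ap an [aperture()].
#' @param mlc list with `transmission`, `leaf_end_radius`,
#'   `leaf_thickness`, `tongue_groove_width` (mm); see [beam_model()].
#' @param jaw_transmission scalar jaw transmission fraction.
#' @return numeric vector of transmission fractions in (0, 1].
#' @export
aperture_transmission <- function(points, ap, mlc, jaw_transmission = 0.002) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  x <- points[, 1]; y <- points[, 2]
  f_jaw <- ifelse(x >= ap$jaw_x[1] & x <= ap$jaw_x[2] &
                    y >= ap$jaw_y[1] & y <= ap$jaw_y[2],
                  1, jaw_transmission)
  f_mlc <- mlc_row_transmission(x, y, ap, mlc)
  if (!is.null(ap$leaf_pairs) && mlc$tongue_groove_width > 0) {
    # near an inter-leaf boundary the more closed neighbor row governs
    edges <- ap$leaf_edges
    inner <- edges[-c(1L, length(edges))]
    if (length(inner)) {
      d <- abs(outer(y, inner, "-"))
      near_i <- apply(d, 1L, which.min)
      near_d <- d[cbind(seq_along(y), near_i)]
      in_strip <- near_d <= mlc$tongue_groove_width / 2
      if (any(in_strip)) {
        yr <- inner[near_i[in_strip]]
        eps <- 1e-6
        f_lo <- mlc_row_transmission(x[in_strip], yr - eps, ap, mlc)
        f_hi <- mlc_row_transmission(x[in_strip], yr + eps, ap, mlc)
        f_mlc[in_strip] <- pmin(f_mlc[in_strip], pmin(f_lo, f_hi))
      }
    }
  }
  pmin(f_jaw * f_mlc, 1)
}

# transmission through the MLC bank alone, by leaf row
mlc_row_transmission <- function(x, y, ap, mlc) {
  if (is.null(ap$leaf_pairs)) return(rep(1, length(x)))
  edges <- ap$leaf_edges
  row <- findInterval(y, edges)
  out <- rep(1, length(x))
  covered <- row >= 1L & row <= nrow(ap$leaf_pairs)
  if (!any(covered)) return(out)
  lt <- ap$leaf_pairs[row[covered], 1]
  rt <- ap$leaf_pairs[row[covered], 2]
  # penetration depth beyond the nearer tip into leaf material
  u <- pmax(lt - x[covered], x[covered] - rt)
  frac <- leaf_end_chord_fraction(u, mlc$leaf_end_radius, mlc$leaf_thickness)
  out[covered] <- mlc$transmission^frac
  out
}

# fraction of full leaf thickness traversed at penetration u behind a
# rounded leaf end of radius R (chord through the end cylinder, capped at
# the physical thickness t)
leaf_end_chord_fraction <- function(u, R, t) {
  u <- pmax(u, 0)
  uc <- pmin(u, R)
  chord <- 2 * sqrt(pmax(uc * (2 * R - uc), 0))
  frac <- pmin(chord / t, 1)
  frac[u >= R] <- 1
  frac
}
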