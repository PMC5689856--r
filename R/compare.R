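#' Extract a central-axis percent depth dose curve
#'
#' Samples the dose trilinearly at 1 mm steps along the beam axis, finds
#' the depth of maximum (ties resolved to the shallowest depth), and
#' normalizes to 100% at a depth 2 to 3 cm beyond d_max (the first sampled
#' depth at least 20 mm past d_max by default).
#'
#' @param dose a [grid3d()] dose grid.
#' @param entry mm position where the axis enters the dose region
#'   (default: on the z axis at the top of the grid).
#' @param direction unit vector of the beam axis (default `-z`).
#' @param step_mm sampling step along the axis.
#' @param normalization_depth override the normalization depth, mm.
#' @return object of class `pdd_curve`: `depths` (mm), `values` (percent),
#'   `d_max`, `normalization_depth`, `dose_at_norm` (Gy).
#' @export
extract_pdd <- function(dose, entry = NULL, direction = c(0, 0, -1),
                        step_mm = 1, normalization_depth = NULL) {
  stopifnot(inherits(dose, "grid3d"))
  direction <- direction / sqrt(sum(direction^2))
  if (is.null(entry)) {
    zmax <- dose$origin[3] + (dim(dose$values)[3] - 1) * dose$spacing[3]
    entry <- c(0, 0, zmax)
  }
  lo <- dose$origin; hi <- dose$origin + (dim(dose$values) - 1) * dose$spacing
  if (any(entry < lo - 1e-9) || any(entry > hi + 1e-9))
    stop("axis entry point lies outside the dose grid")
  span <- sum((hi - lo) * abs(direction))
  depths <- seq(0, span, by = step_mm)
  pts <- cbind(entry[1] + depths * direction[1],
               entry[2] + depths * direction[2],
               entry[3] + depths * direction[3])
  vals <- grid_sample(dose, pts)
  keep <- !is.na(vals)
  depths <- depths[keep]; vals <- vals[keep]
  if (!length(depths)) stop("beam axis does not cross the dose grid")
  d_max <- depths[which.max(vals)]   # which.max takes the shallowest tie
  if (is.null(normalization_depth)) {
    cand <- depths[depths >= d_max + 20]
    normalization_depth <- if (length(cand)) cand[1] else d_max
  }
  ref <- vals[which.min(abs(depths - normalization_depth))]
  if (ref <= 0) stop("zero dose at the normalization depth")
  structure(list(depths = depths, values = 100 * vals / ref, d_max = d_max,
                 normalization_depth = normalization_depth,
                 dose_at_norm = ref),
            class = "pdd_curve")
}

#' @export
print.pdd_curve <- function(x, ...) {
  cat(sprintf("<pdd_curve> %d points, d_max %.0f mm, normalized at %.0f mm\n",
              length(x$depths), x$d_max, x$normalization_depth))
  invisible(x)
}

#' @export
plot.pdd_curve <- function(x, ...) {
  plot(x$depths, x$values, type = "l", xlab = "depth (mm)",
       ylab = "PDD (%)", ...)
  graphics::abline(v = x$d_max, lty = 3)
  invisible(x)
}

#' Mean dose over a spherical region of interest
#'
#' Volume-weighted mean over voxels, with partial voxels handled by 3x3x3
#' subsampling — the chamber-volume ROI readout used for point-dose
#' comparisons.
#'
#' @param dose a [grid3d()].
#' @param center ROI center, mm.
#' @param radius_mm ROI radius, mm (a 0.125 cm^3 chamber is about 3.1 mm).
#' @return mean dose (Gy).
#' @export
roi_mean <- function(dose, center, radius_mm) {
  stopifnot(inherits(dose, "grid3d"), radius_mm > 0)
  ax <- lapply(1:3, function(a) grid_axis(dose, a))
  half_diag <- sqrt(sum((dose$spacing / 2)^2))
  idx <- lapply(1:3, function(a)
    which(abs(ax[[a]] - center[a]) <= radius_mm + half_diag))
  if (!all(lengths(idx) > 0)) stop("ROI lies outside the dose grid")
  cand <- as.matrix(expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]]))
  ctr <- cbind(ax[[1]][cand[, 1]], ax[[2]][cand[, 2]], ax[[3]][cand[, 3]])
  sub <- as.matrix(expand.grid(u = (-1:1) / 3, v = (-1:1) / 3,
                               w = (-1:1) / 3))
  w <- numeric(nrow(cand))
  for (s in seq_len(nrow(sub))) {
    p <- sweep(ctr, 2L, sub[s, ] * dose$spacing, "+")
    inside <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
      (p[, 3] - center[3])^2 <= radius_mm^2
    w <- w + inside
  }
  if (sum(w) == 0) stop("empty ROI: no voxel subsample falls inside")
  v <- dose$values[cand[, c(1, 2, 3), drop = FALSE]]
  sum(v * w) / sum(w)
}

#' Exclude the outermost body layer
#'
#' Morphological erosion of the body mask by a grid-metric ball: the
#' standard way to drop the build-up region (outermost 7 mm of the body)
#' from 3D gamma comparisons.
#'
#' @param body_mask logical array, or a [density_volume()] (its
#'   `body_mask` is used).
#' @param spacing voxel spacing, mm (taken from the volume if one is
#'   given).
#' @param margin_mm erosion radius, mm.
#' @return logical array of retained voxels.
#' @export
surface_exclusion <- function(body_mask, spacing = NULL, margin_mm = 7) {
  if (inherits(body_mask, "density_volume")) {
    spacing <- body_mask$grid$spacing
    body_mask <- body_mask$body_mask
  }
  stopifnot(is.logical(body_mask), length(dim(body_mask)) == 3L,
            margin_mm >= 0, !is.null(spacing))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (margin_mm == 0) return(body_mask)
  cpp_erode(body_mask, spacing, margin_mm)
}

#' Tabulate gamma passing rates for a set of comparisons
#'
#' Runs each comparison at the 2%G/2 mm and 3%G/2 mm criteria (10%
#' low-dose cutoff) and returns one row per comparison, shaped like the
#' per-plan QA summary tables of commissioning reports.
#'
#' @param comparisons non-empty list of entries
#'   `list(plan =, mode =, reference =, evaluated =, mask = NULL)`.
#' @return data.frame with columns `plan`, `mode`, `rate_2G2mm`,
#'   `rate_3G2mm` (percent, full precision).
#' @export
report <- function(comparisons) {
  if (!length(comparisons)) stop("no comparisons given")
  rows <- lapply(comparisons, function(cmp) {
    r2 <- gamma_analysis(cmp$reference, cmp$evaluated,
                         gamma_criteria(2, 2), mask = cmp$mask)
    r3 <- gamma_analysis(cmp$reference, cmp$evaluated,
                         gamma_criteria(3, 2), mask = cmp$mask)
    data.frame(plan = cmp$plan %||% "plan", mode = cmp$mode %||% "",
               rate_2G2mm = r2$passing_rate, rate_3G2mm = r3$passing_rate)
  })
  do.call(rbind, rows)
}

#' Write a passing-rate report
#'
#' CSV output rounds rates to 0.1%; JSON keeps full precision.
#'
#' @param tbl a [report()] data.frame.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return `tbl`, invisibly.
#' @export
write_report <- function(tbl, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    out <- tbl
    out$rate_2G2mm <- sprintf("%.1f", out$rate_2G2mm)
    out$rate_3G2mm <- sprintf("%.1f", out$rate_3G2mm)
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(tbl, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tbl)
}
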