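#' Gamma-analysis acceptance criteria
#'
#' @param dose_pct dose-difference criterion, percent (e.g. 3 or 2).
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param normalization `"global"` (percent of the reference maximum) or
#'   `"local"` (percent of the local reference dose).
#' @param low_dose_cutoff_pct reference voxels below this percentage of
#'   the reference maximum are not evaluated.
#' @return object of class `gamma_criteria`.
#' @examples
#' gamma_criteria(3, 2)          # 3%G/2 mm/10%
#' gamma_criteria(2, 2)          # 2%G/2 mm/10%
#' @export
gamma_criteria <- function(dose_pct = 3, dta_mm = 2,
                           normalization = c("global", "local"),
                           low_dose_cutoff_pct = 10) {
  normalization <- match.arg(normalization)
  stopifnot(dose_pct > 0, dta_mm > 0, low_dose_cutoff_pct > 0)
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 normalization = normalization,
                 low_dose_cutoff_pct = low_dose_cutoff_pct),
            class = "gamma_criteria")
}

gamma_prepare <- function(reference, evaluated, criteria, mask) {
  stopifnot(inherits(reference, "grid3d"), inherits(evaluated, "grid3d"),
            inherits(criteria, "gamma_criteria"))
  rlo <- reference$origin; rhi <- reference$origin +
    (dim(reference$values) - 1) * reference$spacing
  elo <- evaluated$origin; ehi <- evaluated$origin +
    (dim(evaluated$values) - 1) * evaluated$spacing
  if (any(rhi < elo) || any(ehi < rlo))
    stop("reference and evaluated grids do not overlap")
  ref_max <- max(reference$values)
  eval_mask <- reference$values >=
    criteria$low_dose_cutoff_pct / 100 * ref_max
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(reference$values)))
    eval_mask <- eval_mask & mask
  }
  delta <- if (criteria$normalization == "global")
    array(criteria$dose_pct / 100 * ref_max, dim = dim(reference$values))
  else criteria$dose_pct / 100 * pmax(reference$values, 1e-12)
  list(eval_mask = eval_mask, delta = delta)
}

gamma_finish <- function(gmap, reference, criteria) {
  evaluated <- !is.na(gmap)
  n <- sum(evaluated)
  rate <- if (n > 0) 100 * sum(gmap[evaluated] <= 1 + 1e-9) / n else NA_real_
  structure(list(gamma_map = grid3d(ifelse(is.na(gmap), NaN, gmap) + 0,
                                    reference$spacing, reference$origin),
                 passing_rate = rate, n_evaluated = n, criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%%s/%g mm/%g%%: passing rate %.2f%% (n = %d)\n",
              x$criteria$dose_pct,
              if (x$criteria$normalization == "global") "G" else "L",
              x$criteria$dta_mm, x$criteria$low_dose_cutoff_pct,
              x$passing_rate, x$n_evaluated))
  invisible(x)
}

#' 3D gamma analysis
#'
#' For every reference voxel above the low-dose cutoff (and inside `mask`,
#' if given), gamma is the minimum over evaluated positions of
#' `sqrt((dr/dta)^2 + (dD/delta)^2)`, with the evaluated dose trilinearly
#' interpolated on a `dta/10` offset lattice within a search radius of
#' `search_cap * dta`. The reference grid defines the evaluation lattice;
#' the two grids may differ in spacing but must share the frame.
#'
#' @param reference,evaluated [grid3d()] dose grids (Gy) in a common frame.
#' @param criteria a [gamma_criteria()].
#' @param mask optional logical array on the reference grid (e.g. a
#'   [surface_exclusion()] result).
#' @param search_cap search radius in multiples of `dta_mm`.
#' @param step_frac offset lattice step in fractions of `dta_mm`.
#' @return a `gamma_result`: `gamma_map` ([grid3d()], `NaN` where not
#'   evaluated), `passing_rate` (percent of evaluated voxels with
#'   gamma <= 1), `n_evaluated`, `criteria`.
#' @export
gamma_analysis <- function(reference, evaluated, criteria = gamma_criteria(),
                           mask = NULL, search_cap = 3, step_frac = 0.1) {
  prep <- gamma_prepare(reference, evaluated, criteria, mask)
  gmap <- cpp_gamma(reference$values, reference$spacing, reference$origin,
                    evaluated$values, evaluated$spacing, evaluated$origin,
                    prep$delta, as.logical(prep$eval_mask),
                    criteria$dta_mm, search_cap, step_frac, 0L)
  gamma_finish(gmap, reference, criteria)
}

#' Brute-force gamma oracle
#'
#' Exhaustive minimization over the same `dta/10` offset lattice within
#' the `search_cap * dta` radius, in raw scan order with only a lossless
#' dominance prune (offsets whose spatial term alone exceeds the
#' zero-offset gamma cannot improve the minimum). Authoritative within the
#' lattice step; guards against grids that would make exhaustive search
#' unreasonable.
#'
#' @inheritParams gamma_analysis
#' @param max_voxels refuse reference grids larger than this.
#' @return a `gamma_result`.
#' @export
gamma_bruteforce <- function(reference, evaluated,
                             criteria = gamma_criteria(), mask = NULL,
                             search_cap = 3, step_frac = 0.1,
                             max_voxels = 50000) {
  if (prod(dim(reference$values)) > max_voxels)
    stop("grid too large for the brute-force oracle (",
         prod(dim(reference$values)), " voxels)")
  prep <- gamma_prepare(reference, evaluated, criteria, mask)
  gmap <- cpp_gamma(reference$values, reference$spacing, reference$origin,
                    evaluated$values, evaluated$spacing, evaluated$origin,
                    prep$delta, as.logical(prep$eval_mask),
                    criteria$dta_mm, search_cap, step_frac, 1L)
  gamma_finish(gmap, reference, criteria)
}
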