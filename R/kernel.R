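#' Energy-deposition point kernel in water
#'
#' Fraction of the energy released at a primary interaction site that is
#' deposited per (zenith angle, radius) bin around it, tabulated at 1 mm
#' radial and 1 degree angular resolution in water. Monte Carlo vendor
#' kernels are unavailable, so the package ships an analytic surrogate: a
#' forward-peaked exponential family whose angular width and forward range
#' scale with the interaction energy (secondary-electron range roughly
#' 4-5 mm per MeV in water). All engine claims that depend on the kernel
#' are structural (normalization, density scaling, convergence), not
#' fidelity claims to any vendor kernel.
#'
#' @param energy_mev interaction (primary photon) energy, MeV.
#' @param r_max_mm tabulated reach; energy beyond it is folded back by
#'   renormalization.
#' @param dr_mm,dtheta_deg tabulation steps (1 mm, 1 degree defaults).
#' @return object of class `kernel_table`: `zenith_deg` (bin centers),
#'   `radii_mm` (bin edges), matrix `k` (`n_theta x n_r`) summing to 1, and
#'   `energy_mev`.
#' @export
kernel_table <- function(energy_mev, r_max_mm = 60, dr_mm = 1,
                         dtheta_deg = 1) {
  stopifnot(energy_mev > 0, r_max_mm > 0)
  th_edges <- seq(0, 180, by = dtheta_deg) * pi / 180
  th_c <- (th_edges[-1] + th_edges[-length(th_edges)]) / 2
  r_edges <- seq(0, r_max_mm, by = dr_mm)

  # angular weight: forward-peaked, narrower at high energy
  theta0 <- 40 / sqrt(1 + energy_mev) * pi / 180
  w_th <- exp(-th_c / theta0) * (cos(th_edges[-length(th_edges)]) -
                                   cos(th_edges[-1]))
  w_th <- w_th / sum(w_th)

  # radial falloff: exponential with direction-dependent mean range
  r_fwd <- pmax(6 * energy_mev, 2)
  r_bwd <- 1 + 0.15 * energy_mev
  rng <- r_bwd + (r_fwd - r_bwd) * ((1 + cos(th_c)) / 2)^2
  k <- matrix(0, length(th_c), length(r_edges) - 1L)
  for (i in seq_along(th_c)) {
    cdf <- 1 - exp(-r_edges / rng[i])
    p <- diff(cdf) / cdf[length(cdf)]   # renormalize within reach
    k[i, ] <- w_th[i] * p
  }
  structure(list(zenith_deg = th_c * 180 / pi, radii_mm = r_edges, k = k,
                 energy_mev = energy_mev),
            class = "kernel_table")
}

#' Collapsed-cone direction set
#'
#' Discretizes the unit sphere into `n_zenith` zenith bands times
#' `n_azimuth` azimuthal sectors. Cone axes are placed at band centers (the
#' azimuthally symmetric kernel gives each azimuthal copy an equal share).
#' Directions are in the kernel frame: +z is the forward (beam) direction.
#'
#' @param n_zenith,n_azimuth number of zenith bands / azimuthal sectors.
#' @return object of class `cone_set`: `directions` (`n x 3` unit vectors),
#'   `weights` (fractions of 4 pi, summing to 1), `zenith_band` (band index
#'   per cone), `theta_edges_deg`.
#' @export
cone_set <- function(n_zenith = 8, n_azimuth = 6) {
  stopifnot(n_zenith >= 1, n_azimuth >= 1)
  th_edges <- seq(0, 180, length.out = n_zenith + 1L) * pi / 180
  th_c <- (th_edges[-1] + th_edges[-length(th_edges)]) / 2
  phi <- (seq_len(n_azimuth) - 0.5) * 2 * pi / n_azimuth
  dirs <- matrix(0, n_zenith * n_azimuth, 3L)
  band <- integer(n_zenith * n_azimuth)
  wts <- numeric(n_zenith * n_azimuth)
  solid <- (cos(th_edges[-length(th_edges)]) - cos(th_edges[-1])) / 2
  k <- 1L
  for (i in seq_len(n_zenith)) {
    for (j in seq_len(n_azimuth)) {
      dirs[k, ] <- c(sin(th_c[i]) * cos(phi[j]), sin(th_c[i]) * sin(phi[j]),
                     cos(th_c[i]))
      band[k] <- i
      wts[k] <- solid[i] / n_azimuth
      k <- k + 1L
    }
  }
  structure(list(directions = dirs, weights = wts, zenith_band = band,
                 theta_edges_deg = th_edges * 180 / pi),
            class = "cone_set")
}

#' Collapse a fine kernel onto a cone set
#'
#' Sums the 1-degree kernel bins falling in each zenith band and splits the
#' band energy equally among its azimuthal cones (the fine kernel is
#' azimuthally symmetric).
#'
#' @param kernel a [kernel_table()].
#' @param cones a [cone_set()].
#' @return object of class `cone_kernel`: `radii_mm` edges, `k`
#'   (`n_cones x n_r`) with total 1, plus the cone set.
#' @export
collapse_kernel <- function(kernel, cones) {
  stopifnot(inherits(kernel, "kernel_table"), inherits(cones, "cone_set"))
  n_band <- length(cones$theta_edges_deg) - 1L
  band_of_theta <- findInterval(kernel$zenith_deg, cones$theta_edges_deg,
                                rightmost.closed = TRUE)
  band_k <- matrix(0, n_band, ncol(kernel$k))
  for (b in seq_len(n_band))
    band_k[b, ] <- colSums(kernel$k[band_of_theta == b, , drop = FALSE])
  n_az <- sum(cones$zenith_band == 1L)
  k <- band_k[cones$zenith_band, , drop = FALSE] / n_az
  structure(list(radii_mm = kernel$radii_mm, k = k, cones = cones,
                 energy_mev = kernel$energy_mev),
            class = "cone_kernel")
}

#' Cumulative-cumulative kernel table
#'
#' For each cone, cumulates the collapsed kernel over radius (CK, the
#' fraction of total released energy deposited along the cone within
#' radiological radius r) and then cumulates CK once more over radius
#' (CCK). Depositing into a radial interval `[a, b]` via CK differences is
#' exact for piecewise-constant TERMA; the CCK supplies exact bin-averaged
#' CK values over voxel-sized intervals, which suppresses voxelization
#' artifacts.
#'
#' A kernel whose bins do not sum to 1 is renormalized with a warning.
#'
#' @param ck a [collapse_kernel()] result.
#' @return object of class `cck_table`: `radii_mm` edges, matrices `CK` and
#'   `CCK` (`n_cones x n_edges`), the cone set, `cone_total` (per-cone
#'   energy fraction).
#' @export
build_cck <- function(ck) {
  stopifnot(inherits(ck, "cone_kernel"))
  tot <- sum(ck$k)
  k <- ck$k
  if (abs(tot - 1) > 1e-6) {
    warning(sprintf("kernel bins sum to %.6f; renormalizing", tot))
    k <- k / tot
  }
  n_edges <- length(ck$radii_mm)
  CK <- cbind(0, t(apply(k, 1L, cumsum)))
  dr <- diff(ck$radii_mm)
  CCK <- matrix(0, nrow(CK), n_edges)
  for (j in 2:n_edges)
    CCK[, j] <- CCK[, j - 1L] + (CK[, j - 1L] + CK[, j]) / 2 * dr[j - 1L]
  structure(list(radii_mm = ck$radii_mm, CK = CK, CCK = CCK,
                 cones = ck$cones, cone_total = rowSums(k),
                 energy_mev = ck$energy_mev),
            class = "cck_table")
}

#' Energy deposited into a radial interval along one cone
#'
#' `CK(b) - CK(a)` with linear interpolation between tabulated edges;
#' radii beyond the tabulated reach take the cone's total. With
#' `average_over > 0` the CK values are bin-averaged over that window via
#' CCK differences before differencing (the voxelization-suppressing mode).
#'
#' @param cck a [build_cck()] table.
#' @param cone cone index.
#' @param a,b radiological interval, mm (`a <= b`).
#' @param average_over averaging window, mm (0 = raw CK).
#' @return fraction of released energy.
#' @export
cck_deposit <- function(cck, cone, a, b, average_over = 0) {
  stopifnot(a <= b)
  ck_at <- function(r) {
    if (average_over > 0) {
      h <- average_over / 2
      (cck_interp(cck$CCK[cone, ], cck$radii_mm, r + h, cck$cone_total[cone]) -
         cck_interp(cck$CCK[cone, ], cck$radii_mm, r - h,
                    cck$cone_total[cone])) / average_over
    } else {
      stats::approx(cck$radii_mm, cck$CK[cone, ], xout = pmin(pmax(r, 0),
                    max(cck$radii_mm)), rule = 2)$y
    }
  }
  ck_at(b) - ck_at(a)
}

# CCK extended linearly beyond the reach (CK there equals the cone total)
# and clamped to 0 below r = 0
cck_interp <- function(CCKrow, edges, r, total) {
  rmax <- max(edges)
  if (r <= 0) return(0)
  if (r >= rmax)
    return(CCKrow[length(CCKrow)] + (r - rmax) * total)
  stats::approx(edges, CCKrow, xout = r)$y
}

#' Build the energy-indexed CCK family used by the engine
#'
#' Hardening-aware superposition selects, per voxel, the kernel whose
#' tabulated energy is nearest the voxel's TERMA-weighted mean photon
#' energy.
#'
#' @param kernel_energies tabulated kernel energies, MeV.
#' @param cones a [cone_set()].
#' @param r_max_mm kernel reach, mm.
#' @return list of [build_cck()] tables with attribute `energies`.
#' @export
build_cck_family <- function(kernel_energies = c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 8),
                             cones = cone_set(), r_max_mm = 60) {
  fam <- lapply(kernel_energies, function(e)
    build_cck(collapse_kernel(kernel_table(e, r_max_mm = r_max_mm), cones)))
  attr(fam, "energies") <- kernel_energies
  fam
}
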