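#' Photon spectrum on the 16 engine energy bins
#'
#' @param bin_weights fluence fractions per bin, >= 0; normalized to sum 1.
#' @param bin_energies bin energies in MeV, strictly increasing, length 16.
#' @return object of class `spectrum` with `bin_energies`, `bin_weights`.
#' @export
spectrum <- function(bin_weights, bin_energies = energy_bins()) {
  if (length(bin_energies) != 16L || length(bin_weights) != 16L)
    stop("a spectrum has exactly 16 bins")
  if (any(diff(bin_energies) <= 0))
    stop("bin energies must be strictly increasing")
  if (any(bin_weights < 0)) stop("bin weights must be >= 0")
  s <- sum(bin_weights)
  if (s <= 0) stop("spectrum must carry some fluence")
  structure(list(bin_energies = as.numeric(bin_energies),
                 bin_weights = as.numeric(bin_weights) / s),
            class = "spectrum")
}

#' Mean energy of a spectrum (fluence-weighted), MeV
#' @param s a [spectrum()].
#' @export
spectrum_mean_energy <- function(s) sum(s$bin_weights * s$bin_energies)

#' Surrogate linac spectra
#'
#' Vendor beam spectra are commissioning data and are not published; the
#' package ships analytic surrogate spectra per nominal beam quality. Each
#' is a thin-target-like shape `E * exp(-E/Ec)` truncated at the nominal
#' accelerating potential, which reproduces the qualitative ordering of the
#' three beam qualities (softer 6 MV, harder 15 MV, and a soft broad
#' 10 MV FFF).
#'
#' @param energy_label one of `"6MV"`, `"10FFF"`, `"15MV"`.
#' @return a [spectrum()].
#' @examples
#' spectrum_mean_energy(surrogate_spectrum("6MV"))
#' @export
surrogate_spectrum <- function(energy_label = c("6MV", "10FFF", "15MV")) {
  energy_label <- match.arg(energy_label)
  p <- switch(energy_label,
              "6MV"   = list(emax = 6,  ec = 0.85),
              "10FFF" = list(emax = 10, ec = 1.35),
              "15MV"  = list(emax = 15, ec = 2.2))
  e <- energy_bins()
  w <- e * exp(-e / p$ec)
  w[e > p$emax] <- 0
  spectrum(w)
}

#' Surrogate extrafocal (head-scatter) spectrum
#'
#' The extrafocal source is softer than the primary beam; modeled by
#' halving the characteristic energy of the matching primary surrogate.
#' @inheritParams surrogate_spectrum
#' @return a [spectrum()].
#' @export
surrogate_extrafocal_spectrum <- function(energy_label = c("6MV", "10FFF", "15MV")) {
  energy_label <- match.arg(energy_label)
  p <- switch(energy_label,
              "6MV"   = list(emax = 6,  ec = 0.5),
              "10FFF" = list(emax = 10, ec = 0.55),
              "15MV"  = list(emax = 15, ec = 1.1))
  e <- energy_bins()
  w <- e * exp(-e / p$ec)
  w[e > p$emax] <- 0
  spectrum(w)
}
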