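# shared coarse configurations and cached calibrated beams so the engine
# tests stay fast; physics accuracy at these settings is itself under test

coarse_cfg <- function(...) {
  engine_config(fluence_spacing = 2.5, plane_margin = 30, ...)
}

.test_cache <- new.env(parent = emptyenv())

test_water_cube <- function(spacing = 5) {
  key <- paste0("wc", paste(spacing, collapse = "x"))
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- build_water_cube(200, spacing)
  .test_cache[[key]]
}

test_beam <- function(energy = "6MV", cfg = coarse_cfg()) {
  key <- paste0("beam-", energy)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- calibrate_output(beam_model(energy),
                                           test_water_cube(), cfg)
  .test_cache[[key]]
}

# a monoenergetic, single-source fluence map for analytic TERMA checks
mono_fluence <- function(beam, ap, bin = 6L, sad = Inf, spacing = 2.5) {
  fl <- compute_fluence(beam, ap, segment_mu = 1, sad = sad,
                        plane_spacing = spacing, plane_margin = 30)
  w <- rep(0, 16); w[bin] <- 1
  fl$spectrum <- spectrum(w)
  fl$extrafocal <- fl$extrafocal * 0
  fl$contamination <- fl$contamination * 0
  fl
}

# smooth positive random field on a 20^3 grid, dose-like (buildup-free but
# spatially correlated), used for gamma-analysis property tests
smooth_random_grid <- function(n = 20, spacing = 2.5, lo = 1, hi = 3) {
  a <- array(stats::rnorm(n^3), c(n, n, n))
  for (ax in 1:3) {
    a <- (a + a[c(1, 1:(n - 1)), , ] + a[c(2:n, n), , ]) / 3
    a <- aperm(a, c(2, 3, 1))
  }
  a <- a - min(a); a <- a / max(a)
  grid3d(lo + (hi - lo) * a, spacing, origin = rep(-(n - 1) * spacing / 2, 3))
}

perturbed_copy <- function(g, scale_sd = 0.01, noise_sd = 0.01) {
  grid3d(g$values * (1 + stats::rnorm(1, 0, scale_sd)) +
           noise_sd * array(stats::rnorm(length(g$values)),
                            dim = dim(g$values)),
         g$spacing, g$origin)
}
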