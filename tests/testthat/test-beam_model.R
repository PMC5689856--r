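test_that("aperture transmission: open, jaw-blocked and leaf-blocked points", {
  bm <- beam_model("6MV")
  ap <- aperture(c(-50, 50), c(-50, 50))
  expect_equal(aperture_transmission(c(0, 0), ap, bm$mlc,
                                     bm$jaw_transmission), 1.0)
  expect_equal(aperture_transmission(c(80, 0), ap, bm$mlc,
                                     bm$jaw_transmission),
               bm$jaw_transmission)
  # fully closed leaves under an open jaw -> MLC transmission
  apc <- aperture(c(-50, 50), c(-50, 50),
                  leaf_pairs = cbind(rep(0, 40), rep(0, 40)))
  expect_equal(aperture_transmission(c(30, 1.6), apc, bm$mlc,
                                     bm$jaw_transmission),
               bm$mlc$transmission)
})

test_that("rounded leaf-end profile is monotone and matches the chord model", {
  bm <- beam_model("6MV")
  ap <- aperture(c(-100, 100), c(-60, 60),
                 leaf_pairs = cbind(rep(-40, 40), rep(10, 40)))
  xs <- seq(-5, 95, by = 0.1)
  tr <- aperture_transmission(cbind(xs, 1.6), ap, bm$mlc,
                              bm$jaw_transmission)
  expect_true(all(diff(tr) <= 1e-12))
  expect_equal(tr[1], 1.0)
  expect_equal(tr[length(tr)], bm$mlc$transmission)
  # against the independent chord-geometry oracle at several penetrations
  for (u in c(0.5, 2, 5, 20)) {
    frac <- chord_fraction_oracle(u, bm$mlc$leaf_end_radius,
                                  bm$mlc$leaf_thickness)
    expect_equal(
      aperture_transmission(c(10 + u, 1.6), ap, bm$mlc, bm$jaw_transmission),
      bm$mlc$transmission^frac, tolerance = 1e-9)
  }
})

test_that("tongue-and-groove strip takes the more closed neighbor", {
  bm <- beam_model("6MV")
  lp <- cbind(rep(-50, 40), rep(50, 40))
  lp[20, ] <- c(0, 0)    # one closed leaf pair; its row spans y in [-5, 0]
  ap <- aperture(c(-60, 60), c(-60, 60), leaf_pairs = lp)
  t_strip <- aperture_transmission(c(20, 0.2), ap, bm$mlc,
                                   bm$jaw_transmission)
  t_open <- aperture_transmission(c(20, 2.4), ap, bm$mlc,
                                  bm$jaw_transmission)
  expect_equal(t_open, 1.0)
  expect_equal(t_strip, bm$mlc$transmission)
})

test_that("fluence limiting case: flat open field", {
  bm <- beam_model("6MV", extrafocal_fraction = 0,
                   primary_radial_profile = list(r_mm = c(0, 300),
                                                 intensity = c(1, 1)))
  ap <- aperture(c(-50, 50), c(-50, 50))
  fl <- compute_fluence(bm, ap, segment_mu = 1)
  inside <- abs(fl$x) < 45
  outside <- abs(fl$x) > 55
  mid <- which.min(abs(fl$y))
  expect_true(all(abs(fl$primary[inside, mid] - 1) < 1e-9))
  expect_true(all(abs(fl$primary[outside, mid] - bm$jaw_transmission) < 1e-9))
  expect_true(all(fl$extrafocal == 0))
})

test_that("extrafocal channel is reduced for small apertures", {
  bm <- beam_model("6MV")
  f3 <- compute_fluence(bm, aperture(c(-15, 15), c(-15, 15)), 1)
  f10 <- compute_fluence(bm, aperture(c(-50, 50), c(-50, 50)), 1)
  ef_ctr <- function(f) f$extrafocal[which.min(abs(f$x)),
                                     which.min(abs(f$y))]
  expect_lt(ef_ctr(f3), ef_ctr(f10))
  # and it spills beyond the geometric edge
  edge_out <- which.min(abs(f10$x - 55))
  expect_gt(f10$extrafocal[edge_out, which.min(abs(f10$y))],
            bm$extrafocal_fraction * bm$jaw_transmission)
})

test_that("fluence is linear in MU and mirror symmetric", {
  bm <- beam_model("10FFF")
  ap <- aperture(c(-40, 40), c(-40, 40))
  f1 <- compute_fluence(bm, ap, 1)
  f2 <- compute_fluence(bm, ap, 2)
  for (ch in c("primary", "extrafocal", "contamination"))
    expect_equal(f2[[ch]], 2 * f1[[ch]], tolerance = 1e-12)
  asym <- max(abs(f1$primary - f1$primary[nrow(f1$primary):1, ])) /
    max(f1$primary)
  expect_lt(asym, 1e-6)
  expect_true(all(f1$primary > 0))   # transmission floors, never zero
})

test_that("output calibration is idempotent and linear in dose_per_mu", {
  cfg <- coarse_cfg()
  wc <- test_water_cube()
  bm <- calibrate_output(beam_model("6MV"), wc, cfg)
  bm2 <- calibrate_output(bm, wc, cfg)
  expect_equal(attr(bm2, "scale_factor"), 1.0, tolerance = 1e-6)
  bmx <- calibrate_output(beam_model("6MV", dose_per_mu = 0.02), wc, cfg)
  expect_equal(bmx$output_scale / bm$output_scale, 2.0, tolerance = 1e-9)
})
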