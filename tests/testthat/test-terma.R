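test_that("radiological path: uniform, slab, degenerate", {
  wc <- build_water_cube(100, spacing = 5)
  # cube spans z in [0, 100]; a vertical ray of 50 mm inside water
  expect_equal(radiological_path(wc, c(0, 0, 200), c(0, 0, 50)), 50,
               tolerance = 1e-9)
  expect_equal(radiological_path(wc, c(0, 0, 10), c(0, 0, 10)), 0)
  slab <- build_slab_phantom(spacing = 5)
  expect_equal(radiological_path(slab, c(0, 0, 100), c(0, 0, 0)), 65,
               tolerance = 1e-9)
})

test_that("oblique radiological paths agree with dense-sampling oracle", {
  set.seed(21)
  n <- c(14, 12, 10)
  g <- grid3d(array(stats::runif(prod(n), 0, 2), n), c(4, 5, 6),
              origin = c(-26, -27.5, -27))
  dv <- density_volume(g, array(TRUE, n))
  for (i in 1:6) {
    src <- stats::runif(3, -80, 80)
    dst <- stats::runif(3, -20, 20)
    got <- radiological_path(dv, src, dst)
    want <- rad_path_oracle(dv, src, dst)
    expect_equal(got, want, tolerance = 1e-3 * max(want, 1))
  }
})

test_that("monoenergetic parallel-beam TERMA matches exp(-mu d)", {
  wc <- test_water_cube(2.5)
  bm <- beam_model("6MV")
  fl <- mono_fluence(bm, aperture(c(-50, 50), c(-50, 50)))
  tm <- compute_terma(fl, wc, inv_sq = FALSE,
                      mu_mm_override = rep(0.005, 16),
                      release_uniform = TRUE)
  z <- seq(98.75, -98.75, by = -2.5)
  ax <- grid_sample(tm$grid, cbind(0, 0, z))
  depth <- 100 - z
  expect_lt(max(abs(ax / ax[1] / exp(-0.005 * (depth - depth[1])) - 1)),
            0.002)
  # TERMA ratio to the surface at depth 100 mm is e^-0.5 (log-linear fit)
  slope <- stats::coef(stats::lm(log(ax) ~ depth))[[2]]
  expect_equal(exp(100 * slope), exp(-0.5), tolerance = 0.002)
})

test_that("inverse square gives a 4:1 ratio for doubled distance", {
  # long thin water column from the isocenter plane downstream so that
  # source distances 1000 and 2000 mm are both inside
  n <- c(9, 9, 101)
  g <- grid3d(1.0, c(10, 10, 10), origin = c(-40, -40, -1000), dims = n)
  dv <- density_volume(g, array(TRUE, n))
  bm <- beam_model("6MV")
  fl <- mono_fluence(bm, aperture(c(-45, 45), c(-45, 45)), sad = 1000,
                     spacing = 2.5)
  tm <- compute_terma(fl, dv, inv_sq = TRUE, mu_mm_override = rep(0, 16),
                      release_uniform = TRUE)
  v_iso <- grid_sample(tm$grid, c(0, 0, 0))      # 1000 mm from source
  v_2x <- grid_sample(tm$grid, c(0, 0, -1000))   # 2000 mm from source
  expect_equal(v_iso / v_2x, 4.0, tolerance = 0.001)
})

test_that("bin-wise attenuation hardens the spectrum with depth", {
  wc <- test_water_cube(2.5)
  bm <- beam_model("6MV")
  fl <- compute_fluence(bm, aperture(c(-50, 50), c(-50, 50)), 1,
                        plane_spacing = 2.5)
  tm <- compute_terma(fl, wc)
  me <- grid_sample(tm$mean_energy, cbind(0, 0, seq(98.75, -98.75, by = -2.5)))
  expect_true(all(diff(me) > 0))
})

test_that("TERMA is non-increasing along the axis once divergence is removed", {
  wc <- test_water_cube(2.5)
  bm <- beam_model("15MV")
  fl <- compute_fluence(bm, aperture(c(-40, 40), c(-40, 40)), 1,
                        plane_spacing = 2.5, sad = Inf)
  tm <- compute_terma(fl, wc, inv_sq = FALSE)
  ax <- grid_sample(tm$grid, cbind(0, 0, seq(98.75, -98.75, by = -2.5)))
  expect_true(all(diff(ax) < 0))
})

test_that("TERMA at a water-equivalent depth is slab-partition invariant", {
  set.seed(22)
  bm <- beam_model("6MV")
  ap <- aperture(c(-40, 40), c(-40, 40))
  profile_vs_we <- function(eds) {
    n <- c(17, 17, 60)
    edz <- rep(eds, each = 10)         # ED by 50 mm depth layer, surface first
    vals <- array(rep(rev(edz), each = n[1] * n[2]), dim = n)
    g <- grid3d(vals, 5, origin = c(-40, -40, 100 - 5 * n[3]) + 2.5)
    dv <- density_volume(g, array(TRUE, n))
    fl <- mono_fluence(bm, ap)
    tm <- compute_terma(fl, dv, inv_sq = FALSE, release_uniform = TRUE)
    t_ax <- grid_sample(tm$grid, cbind(0, 0, rev(grid_axis(g, 3))))
    dwe <- cumsum(edz) * 5 - 2.5 * edz  # WE depth at voxel centers
    # with a uniform release factor, TERMA is a function of WE depth alone
    list(dwe = dwe, t = t_ax)
  }
  a <- profile_vs_we(stats::runif(6, 0.2, 1.5))
  b <- profile_vs_we(stats::runif(6, 0.2, 1.5))
  common <- seq(5, min(max(a$dwe), max(b$dwe)) - 5, by = 5)
  ta <- stats::approx(a$dwe, a$t, xout = common)$y
  tb <- stats::approx(b$dwe, b$t, xout = common)$y
  expect_lt(max(abs(ta / tb - 1)), 0.02)
})

test_that("arc TERMA bookkeeping: 180 evaluations, MU conserved", {
  wc <- test_water_cube(10)
  bm <- beam_model("6MV")
  arc <- build_arc_plan(2, total_mu = 123, side_cm = 8)
  tfa <- terma_for_arc(arc, wc, bm, fluence_spacing = 8, plane_margin = 15)
  expect_length(tfa, 180L)
  expect_equal(sum(vapply(tfa, function(x) x$mu, 0)), 123, tolerance = 1e-9)
  # static plan degenerates to one TERMA per beam
  st <- build_square_field_plan(5, mu = 10)
  tst <- terma_for_arc(st, wc, bm, fluence_spacing = 8, plane_margin = 15)
  expect_length(tst, 1L)
})
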