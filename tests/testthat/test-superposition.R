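test_that("compiled collection superposition matches the plain-R oracle", {
  set.seed(31)
  n <- c(10, 10, 10)
  g <- grid3d(array(stats::runif(prod(n), 0.2, 1.5), n), 5,
              origin = c(-22.5, -22.5, -22.5))
  dv <- density_volume(g, array(TRUE, n))
  bm <- beam_model("6MV")
  fl <- mono_fluence(bm, aperture(c(-20, 20), c(-20, 20)))
  tm <- compute_terma(fl, dv, inv_sq = FALSE, release_uniform = TRUE)
  cck <- build_cck(collapse_kernel(kernel_table(2), cone_set(2, 4)))
  fam <- list(cck); attr(fam, "energies") <- 2
  got <- superpose(tm, dv, fam, tilt = FALSE, step_mm = 5,
                   contamination = FALSE)
  want <- superpose_oracle(tm, dv, cck, step_mm = 5)
  expect_lt(max(abs(got$values - want)) / max(want), 1e-10)
})

test_that("point-kernel dose falloff along a cone axis matches the kernel", {
  # point-like TERMA in fine uniform water; the dose ratio between two
  # distances along a cone axis must reproduce the CK bin ratio
  n <- c(41, 41, 41)
  g <- grid3d(1.0, 1, origin = c(-20, -20, -20), dims = n)
  dv <- density_volume(g, array(TRUE, n))
  cones <- cone_set(8, 6)
  cck <- build_cck(collapse_kernel(kernel_table(2), cones))
  fam <- list(cck); attr(fam, "energies") <- 2
  tm <- structure(list(
    grid = grid3d(0, 1, g$origin, dims = n),
    mean_energy = grid3d(2, 1, g$origin, dims = n),
    contamination = grid3d(0, 1, g$origin, dims = n),
    geom = beam_geometry(0, Inf), mu = 1), class = "terma_grid")
  tm$grid$values[21, 21, 21] <- 1
  d <- superpose(tm, dv, fam, tilt = FALSE, step_mm = 1,
                 contamination = FALSE)
  u <- cones$directions[1, ]           # most forward cone (world -z after
  u <- c(u[1], -u[2], -u[3])           # the gantry-0 base rotation)
  p10 <- round(c(0, 0, 0) + 10 * u)
  p20 <- round(c(0, 0, 0) + 20 * u)
  d10 <- d$values[21 + p10[1], 21 + p10[2], 21 + p10[3]]
  d20 <- d$values[21 + p20[1], 21 + p20[2], 21 + p20[3]]
  r10 <- sqrt(sum(p10^2)); r20 <- sqrt(sum(p20^2))
  want <- cck_deposit(cck, 1, r10 - 0.5, r10 + 0.5) /
    cck_deposit(cck, 1, r20 - 0.5, r20 + 0.5)
  expect_lt(abs(d10 / d20 / want - 1), 0.05)
})

test_that("energy is conserved when the kernel reach is contained", {
  n <- c(40, 40, 60)
  g <- grid3d(1.0, 5, origin = c(-100, -100, -200) + 2.5, dims = n)
  dv <- density_volume(g, array(TRUE, n))
  bm <- beam_model("6MV")
  fl <- mono_fluence(bm, aperture(c(-15, 15), c(-15, 15)))
  tm <- compute_terma(fl, dv, inv_sq = FALSE,
                      mu_mm_override = rep(0.03, 16),
                      release_uniform = TRUE)
  fam <- build_cck_family(1, cone_set(8, 6), 60)
  d <- superpose(tm, dv, fam, tilt = FALSE, contamination = FALSE)
  ratio <- mass_weighted_sum(d, dv) / mass_weighted_sum(tm$grid, dv)
  expect_equal(ratio, 1.0, tolerance = 0.01)
})

test_that("O'Connor density scaling holds for a parallel beam", {
  bm <- beam_model("6MV")
  fam <- build_cck_family(1, cone_set(8, 6), 60)
  run <- function(ed, sp) {
    n <- c(30, 30, 48)
    g <- grid3d(ed, sp, origin = c(-15 * sp, -15 * sp, 100 - 48 * sp) + sp / 2,
                dims = n)
    dv <- density_volume(g, array(TRUE, n))
    fl <- mono_fluence(bm, aperture(c(-40, 40), c(-40, 40)))
    tm <- compute_terma(fl, dv, inv_sq = FALSE, release_uniform = TRUE)
    superpose(tm, dv, fam, tilt = FALSE, contamination = FALSE)
  }
  dw <- run(1.0, 5)
  dh <- run(0.5, 10)
  dep <- seq(10, 180, by = 10)
  pw <- grid_sample(dw, cbind(0, 0, 100 - dep))
  ph <- grid_sample(dh, cbind(0, 0, 100 - 2 * dep))
  expect_lt(max(abs(ph / pw - 1)), 0.01)
})

test_that("dose is linear in MU and two half-segments equal one segment", {
  cfg <- coarse_cfg()
  wc <- test_water_cube()
  bm <- test_beam("6MV", cfg)
  p100 <- build_square_field_plan(5, "6MV", mu = 100)
  p2x50 <- p100
  p2x50$beams <- list(modifyList(p100$beams[[1]], list(mu = 50)),
                      modifyList(p100$beams[[1]], list(mu = 50)))
  d100 <- calc_plan_dose(p100, wc, bm, cfg)
  d2x50 <- calc_plan_dose(p2x50, wc, bm, cfg)
  expect_lt(max(abs(d2x50$values - d100$values)) / max(d100$values), 1e-9)
  expect_true(all(d100$values >= 0))
  p1 <- build_square_field_plan(5, "6MV", mu = 1)
  d1 <- calc_plan_dose(p1, wc, bm, cfg)
  expect_lt(max(abs(100 * d1$values - d100$values)) / max(d100$values), 1e-6)
})

test_that("water-cube PDD rises to a maximum then falls; d_max orders with energy", {
  cfg <- coarse_cfg()
  wc <- test_water_cube(c(5, 5, 2.5))
  dmax <- sapply(c("6MV", "10FFF", "15MV"), function(e) {
    bm <- calibrate_output(beam_model(e), test_water_cube(), cfg)
    d <- calc_plan_dose(build_square_field_plan(10, e, 100), wc, bm, cfg)
    p <- extract_pdd(d)
    rising <- p$values[p$depths <= p$d_max]
    falling <- p$values[p$depths >= p$d_max + 2 & p$depths <= 195]
    expect_gt(p$d_max, 2)
    expect_true(all(diff(rising) >= -0.2))  # no dip beyond 0.2% while rising
    expect_true(all(diff(falling) < 0.002))   # no local maxima > 0.2%
    p$d_max
  })
  expect_true(all(diff(dmax) > 0))
})

test_that("refining the cone set changes the PDD beyond build-up by < 1%", {
  wc <- test_water_cube()
  plan <- build_square_field_plan(10, "6MV", 100)
  # dose restricted to the central axis region keeps this affordable
  mask <- array(FALSE, dim(wc$grid$values))
  ax <- abs(grid_axis(wc$grid, 1)) <= 30
  mask[ax, ax, ] <- TRUE
  run <- function(nz, na) {
    cfg <- coarse_cfg(n_zenith = nz, n_azimuth = na)
    bm <- calibrate_output(beam_model("6MV"), wc, cfg)
    extract_pdd(calc_plan_dose(plan, wc, bm, cfg, mask = mask))
  }
  p1 <- run(8, 6)
  p2 <- run(16, 12)
  sel <- p1$depths > p1$d_max + 5 & p1$depths < 190
  expect_lt(max(abs(p1$values[sel] - p2$values[sel])), 1)
})

test_that("parallel-opposed beams give a mirror-symmetric dose", {
  cfg <- coarse_cfg()
  wc <- test_water_cube()
  bm <- test_beam("6MV", cfg)
  plan <- build_square_field_plan(10, "6MV", 50)
  plan$beams <- c(plan$beams,
                  list(modifyList(plan$beams[[1]], list(gantry_deg = 180))))
  d <- calc_plan_dose(plan, wc, bm, cfg)
  v <- d$values
  asym <- max(abs(v - v[, , dim(v)[3]:1])) / max(v)
  expect_lt(asym, 0.005)
})

test_that("output factor grows with field size; empty plan warns", {
  cfg <- coarse_cfg()
  wc <- test_water_cube()
  bm <- test_beam("6MV", cfg)
  ctr <- sapply(c(5, 10, 20), function(s) {
    d <- calc_plan_dose(build_square_field_plan(s, "6MV", 100), wc, bm, cfg)
    grid_sample(d, c(0, 0, 0))
  })
  expect_true(all(diff(ctr) > 0))
  empty <- build_square_field_plan(5); empty$beams <- list()
  expect_warning(dz <- calc_plan_dose(empty, wc, bm, cfg), "empty plan")
  expect_true(all(dz$values == 0))
  expect_error(calc_plan_dose(build_square_field_plan(5), wc,
                              beam_model("6MV"), cfg), "uncalibrated")
})
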