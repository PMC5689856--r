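test_that("gamma of identical grids is zero with a 100% passing rate", {
  set.seed(41)
  ref <- smooth_random_grid()
  r <- gamma_analysis(ref, ref, gamma_criteria(3, 2))
  expect_equal(r$passing_rate, 100)
  expect_true(all(r$gamma_map$values[!is.nan(r$gamma_map$values)] == 0))
  expect_gt(r$n_evaluated, 0)
  # voxels below the low-dose cutoff are NaN
  lowcut <- ref$values < 0.1 * max(ref$values)
  if (any(lowcut)) expect_true(all(is.nan(r$gamma_map$values[lowcut])))
})

test_that("a uniform dose scaled by exactly the criterion gives gamma 1", {
  ref <- grid3d(2.0, 2.5, c(0, 0, 0), dims = c(12, 12, 12))
  ev <- grid3d(2.0 * 1.03, 2.5, c(0, 0, 0), dims = c(12, 12, 12))
  r <- gamma_analysis(ref, ev, gamma_criteria(3, 2, "global"))
  expect_equal(max(r$gamma_map$values, na.rm = TRUE), 1.0, tolerance = 1e-9)
})

test_that("optimized gamma equals the brute-force oracle", {
  set.seed(42)
  for (i in 1:3) {
    ref <- smooth_random_grid()
    ev <- perturbed_copy(ref)
    go <- gamma_analysis(ref, ev, gamma_criteria(3, 2))
    gb <- gamma_bruteforce(ref, ev, gamma_criteria(3, 2))
    expect_lt(max(abs(go$gamma_map$values - gb$gamma_map$values),
                  na.rm = TRUE), 0.01)
    expect_equal(go$passing_rate, gb$passing_rate, tolerance = 1e-9)
  }
  big <- grid3d(1, 1, c(0, 0, 0), dims = c(60, 60, 60))
  expect_error(gamma_bruteforce(big, big), "too large")
})

test_that("linear-field translations give the analytic gamma", {
  # uniform gradient along x: 0.5%/mm of the 2 Gy plateau
  n <- 31L
  xs <- seq(-37.5, 37.5, by = 2.5)
  ref <- grid3d(array(rep(2 + 0.01 * xs, times = n * n), c(n, n, n)),
                2.5, c(-37.5, -37.5, -37.5))
  shift_by <- function(s) grid3d(
    array(rep(2 + 0.01 * (xs - s), times = n * n), c(n, n, n)),
    2.5, ref$origin)
  interior <- array(FALSE, dim(ref$values))
  interior[8:24, 8:24, 8:24] <- TRUE
  # translation by exactly dta with a tight dose criterion: the shift must
  # be resolved spatially, so gamma = shift/dta = 1
  r1 <- gamma_bruteforce(ref, shift_by(2), gamma_criteria(0.05, 2, "local",
                                                          low_dose_cutoff_pct = 1),
                         mask = interior)
  expect_equal(stats::median(r1$gamma_map$values, na.rm = TRUE), 1.0,
               tolerance = 0.01)
  # translation by 2*dta with a tight dose criterion: gamma = 2
  r2 <- gamma_bruteforce(ref, shift_by(4), gamma_criteria(0.05, 2, "local",
                                                          low_dose_cutoff_pct = 1),
                         mask = interior)
  expect_equal(stats::median(r2$gamma_map$values, na.rm = TRUE), 2.0,
               tolerance = 0.01)
})

test_that("gamma is invariant to joint rigid translation and joint scaling", {
  set.seed(43)
  ref <- smooth_random_grid()
  ev <- perturbed_copy(ref)
  r0 <- gamma_analysis(ref, ev, gamma_criteria(3, 2))
  mv <- function(g, t) grid3d(g$values, g$spacing, g$origin + t)
  rt <- gamma_analysis(mv(ref, c(7, -3, 11)), mv(ev, c(7, -3, 11)),
                       gamma_criteria(3, 2))
  expect_equal(rt$gamma_map$values, r0$gamma_map$values, tolerance = 1e-12)
  sc <- function(g, f) grid3d(g$values * f, g$spacing, g$origin)
  rs <- gamma_analysis(sc(ref, 5.5), sc(ev, 5.5), gamma_criteria(3, 2))
  expect_equal(rs$passing_rate, r0$passing_rate, tolerance = 1e-9)
})

test_that("tighter criteria never increase the passing rate", {
  set.seed(44)
  for (i in 1:5) {
    ref <- smooth_random_grid()
    ev <- perturbed_copy(ref, scale_sd = 0.02, noise_sd = 0.03)
    r3 <- gamma_analysis(ref, ev, gamma_criteria(3, 2))
    r2 <- gamma_analysis(ref, ev, gamma_criteria(2, 2))
    expect_gte(r3$passing_rate, r2$passing_rate)
  }
})

test_that("PDD extraction normalizes beyond d_max and flags geometry errors", {
  cfg <- coarse_cfg()
  wc <- test_water_cube()
  bm <- test_beam("6MV", cfg)
  d <- calc_plan_dose(build_square_field_plan(10, "6MV", 100), wc, bm, cfg)
  p <- extract_pdd(d)
  expect_equal(p$values[match(p$normalization_depth, p$depths)], 100)
  expect_gte(p$normalization_depth, p$d_max + 20)
  expect_error(extract_pdd(d, entry = c(500, 0, 0)), "outside")
})

test_that("roi_mean: uniform, gradient symmetry, Monte Carlo oracle", {
  u <- grid3d(2.0, 2.5, c(-25, -25, -25), dims = c(21, 21, 21))
  expect_equal(roi_mean(u, c(0, 0, 0), 6), 2.0)
  xs <- seq(-25, 25, by = 2.5)
  grad <- grid3d(array(rep(5 + 0.1 * xs, times = 21 * 21), c(21, 21, 21)),
                 2.5, c(-25, -25, -25))
  expect_equal(roi_mean(grad, c(0, 0, 0), 8), 5.0, tolerance = 1e-3)
  set.seed(45)
  f <- smooth_random_grid(n = 21, spacing = 2.5)
  got <- roi_mean(f, c(2, -1, 3), 9)
  # 1e6-point Monte Carlo volume average
  pts <- matrix(stats::runif(3e6, -1, 1), ncol = 3) * 9
  pts <- pts[rowSums(pts^2) <= 81, , drop = FALSE]
  pts <- sweep(pts, 2, c(2, -1, 3), "+")
  mc <- mean(grid_sample(f, pts, rule = "clamp"))
  expect_equal(got, mc, tolerance = 0.002 * abs(mc))
  expect_error(roi_mean(u, c(500, 0, 0), 5), "outside")
})

test_that("surface exclusion erodes by a grid-metric ball", {
  xs <- seq(-51, 51, by = 1.5)
  n <- length(xs)
  m <- array(outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= 50^2, c(n, n, n))
  expect_identical(surface_exclusion(m, 1.5, 0), m)
  er <- surface_exclusion(m, 1.5, 7)
  expect_lt(abs(sum(er) * 1.5^3 / (4 / 3 * pi * 43^3) - 1), 0.05)
  expect_equal(sum(surface_exclusion(m, 1.5, 60)), 0)
  # works straight from a density volume
  th <- build_thorax_phantom(spacing = 5)
  er2 <- surface_exclusion(th$density, margin_mm = 7)
  expect_lt(sum(er2), sum(th$density$body_mask))
})

test_that("report tabulates paired criteria and formats output", {
  set.seed(46)
  ref <- smooth_random_grid()
  tbl <- report(list(list(plan = "identity", mode = "static",
                          reference = ref, evaluated = ref)))
  expect_equal(tbl$rate_2G2mm, 100)
  expect_equal(tbl$rate_3G2mm, 100)
  expect_error(report(list()), "no comparisons")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  ev <- perturbed_copy(ref, 0.02, 0.04)
  tbl2 <- report(list(list(plan = "p", mode = "arc",
                           reference = ref, evaluated = ev)))
  write_report(tbl2, csv, js)
  txt <- read.csv(csv, colClasses = "character")
  expect_match(txt$rate_3G2mm[1], "^[0-9]+\\.[0-9]$")   # rounded to 0.1
  full <- jsonlite::fromJSON(js)
  expect_equal(full$rate_3G2mm[1], tbl2$rate_3G2mm, tolerance = 1e-12)
})
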