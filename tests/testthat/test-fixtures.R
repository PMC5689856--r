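test_that("water cube phantom has the right size and density", {
  wc <- build_water_cube()
  expect_equal(dim(wc$grid$values), c(80L, 80L, 80L))  # 200 mm / 2.5 mm
  expect_true(all(wc$grid$values == 1.0))
  expect_true(all(wc$body_mask))
  expect_equal(grid_sample(wc$grid, c(0, 0, 0)), 1.0)
  expect_error(build_water_cube(0), "> 0")
})

test_that("slab phantom layers sit at the stated depths", {
  slab <- build_slab_phantom(spacing = 5)
  # depth = 100 - z; entry surface at z = +100
  expect_equal(grid_sample(slab$grid, c(0, 0, 100 - 25)), 1.0)
  expect_equal(grid_sample(slab$grid, c(0, 0, 100 - 75)), 0.3)
  expect_equal(grid_sample(slab$grid, c(0, 0, 100 - 150)), 1.0)
  # radiological depth of geometric depth 100 mm: 50*1.0 + 50*0.3
  expect_equal(radiological_path(slab, c(0, 0, 100), c(0, 0, 0)), 65,
               tolerance = 1e-9)
})

test_that("thorax phantom reproduces densities and target volume", {
  th <- build_thorax_phantom(spacing = 2.5)
  # target center is at the isocenter
  expect_equal(grid_sample(th$density$grid, c(0, 0, 0)), 1.0)
  # left lung center (target-centered frame shifts body by -75 mm in x)
  expect_equal(grid_sample(th$density$grid, c(-150, 0, 0)), 0.21)
  nm <- vapply(th$structures$structures, function(s) s$name, "")
  expect_setequal(nm, c("body", "lungs", "target"))
  tv <- sum(th$structures$structures[[which(nm == "target")]]$mask) * 2.5^3
  expect_lt(abs(tv / (4 / 3 * pi * 20^3) - 1), 0.05)
  # without target: lung voxel at lung center
  th2 <- build_thorax_phantom(spacing = 5, with_target = FALSE)
  expect_equal(grid_sample(th2$density$grid, c(75, 0, 0)), 0.21)
})

test_that("phantom builders are deterministic and spacing-consistent", {
  a <- build_slab_phantom(spacing = 5)
  b <- build_slab_phantom(spacing = 5)
  expect_identical(a$grid$values, b$grid$values)
  # mass in a fixed region changes < 2% when halving the spacing
  mass_in_box <- function(dv, lo, hi) {
    g <- dv$grid
    sel <- lapply(1:3, function(ax) {
      x <- grid_axis(g, ax); x >= lo[ax] & x <= hi[ax]
    })
    sum(g$values[sel[[1]], sel[[2]], sel[[3]]]) * prod(g$spacing)
  }
  for (build in list(build_slab_phantom,
                     function(s) build_thorax_phantom(s)$density)) {
    m1 <- mass_in_box(build(5), c(-60, -60, -60), c(60, 60, 60))
    m2 <- mass_in_box(build(2.5), c(-60, -60, -60), c(60, 60, 60))
    expect_lt(abs(m2 / m1 - 1), 0.02)
  }
})

test_that("square-field plans set jaws and MLC apertures", {
  p <- build_square_field_plan(10)
  expect_equal(p$beams[[1]]$jaw_x, c(-50, 50))
  expect_null(p$beams[[1]]$leaf_pairs)

  p3 <- build_square_field_plan(10, mlc_side_cm = 3)
  lp <- p3$beams[[1]]$leaf_pairs
  open <- lp[, 2] > lp[, 1]
  expect_equal(sum(open), 6L)            # 30 mm / 5 mm leaves
  expect_equal(max(lp[, 2]), 15)
  expect_error(build_square_field_plan(-1), "> 0")
})

test_that("five-beam lung plan geometry matches the protocol", {
  p <- build_five_beam_lung_plan()
  expect_equal(vapply(p$beams, function(b) b$gantry_deg, 0),
               c(0, 72, 144, 216, 288))
  mus <- vapply(p$beams, function(b) b$mu, 0)
  expect_true(all(mus == mus[1]))        # equally weighted
  # aperture = 20 mm target radius + 7 mm margin
  widest <- max(p$beams[[1]]$leaf_pairs[, 2])
  expect_lt(abs(widest - 27), 2.5)       # within half a leaf width
  ctr_row <- which.max(p$beams[[1]]$leaf_pairs[, 2])
  expect_equal(p$beams[[1]]$leaf_pairs[ctr_row, 2],
               -p$beams[[1]]$leaf_pairs[ctr_row, 1])
})

test_that("arc plans follow the inclusive control-point convention", {
  arc <- build_arc_plan(2, total_mu = 200)
  expect_equal(length(arc$beams), 181L)
  expect_equal(sum(vapply(arc$beams, function(b) b$mu, 0)), 200)
  expect_error(build_arc_plan(7), "divide 360")
})
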