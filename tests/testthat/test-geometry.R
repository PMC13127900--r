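# Geometry oracles: closed-form sphere/ellipsoid formulas and independent
# quadrature are the reference for every mesh-based estimate.

ball_label_fun <- function(r) function(x, y, z)
  ifelse(x^2 + y^2 + z^2 < r^2, 1L, 0L)

test_that("sphericity formula: sphere identity, scaling law, errors", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-12)
  # halving V at constant A multiplies sphericity by 2^(-2/3)
  V <- 5e5; A <- 4e4
  expect_equal(sphericity(V / 2, A) / sphericity(V, A), 2^(-2 / 3),
               tolerance = 1e-12)
  expect_error(sphericity(0, 1), "positive")
  expect_error(sphericity(1, -1), "positive")
})

test_that("ellipsoid quadrature matches the exact prolate closed form", {
  # prolate spheroid a > b = c: A = 2 pi b^2 (1 + a asin(e) / (b e))
  a <- 60; b <- 30
  e <- sqrt(1 - (b / a)^2)
  exact <- 2 * pi * b^2 * (1 + a * asin(e) / (b * e))
  expect_equal(ellipsoid_surface_area(a, b, b), exact, tolerance = 1e-5)
  # sphere degenerate case
  expect_equal(ellipsoid_surface_area(40, 40, 40), 4 * pi * 40^2,
               tolerance = 1e-6)
})

test_that("digitized ball measures match closed forms (gap-aware grid)", {
  geom <- grid_geometry()   # 2.4 x 2.4 x 6 mm, 10 mm spacing
  labs <- rasterize_to_slices(ball_label_fun(40), c(64, 64, 12), geom)
  mf <- measure_frame(labs, geom)
  V_true <- 4 / 3 * pi * 40^3   # 2.6808e5 mm^3
  A_true <- 4 * pi * 40^2       # 2.0106e4 mm^2
  expect_lt(abs(mf$placental_volume_mm3 / V_true - 1), 0.03)
  expect_lt(abs(mf$placental_surface_area_mm2 / A_true - 1), 0.05)
})

test_that("2:1:1 ellipsoid area matches the quadrature oracle within 5%", {
  geom <- grid_geometry()
  f <- function(x, y, z) ifelse((x / 60)^2 + (y / 30)^2 + (z / 30)^2 < 1,
                                1L, 0L)
  labs <- rasterize_to_slices(f, c(64, 64, 12), geom)
  m <- mask_mesh(labs == 1, geom$voxel_size_mm, geom$slice_spacing_mm)
  expect_lt(abs(m$area_mm2 / ellipsoid_surface_area(60, 30, 30) - 1), 0.05)
  # its sphericity must lie strictly inside (0, 1)
  V <- 4 / 3 * pi * 60 * 30 * 30   # 2.2619e5 mm^3
  psi <- sphericity(V, ellipsoid_surface_area(60, 30, 30))
  expect_gt(psi, 0); expect_lt(psi, 1)
})

test_that("all-background frame gives zero measures with a flag", {
  geom <- grid_geometry()
  labs <- array(0L, c(16, 16, 6))
  expect_warning(mf <- measure_frame(labs, geom), "empty placenta")
  expect_equal(mf$placental_volume_mm3, 0)
  expect_equal(mf$placental_surface_area_mm2, 0)
  expect_true(mf$empty_placenta)
})

test_that("volume estimator is exactly linear in voxel count", {
  geom <- grid_geometry(c(2, 2, 5), 8)
  vox <- 2 * 2 * 8
  for (seed in 1:3) {
    labs <- uterodyn:::with_seed(seed, {
      array(sample(0:3, 10 * 10 * 4, replace = TRUE), c(10, 10, 4))
    })
    mf <- measure_frame(labs, geom, measures = "volumes")
    expect_identical(mf$placental_volume_mm3, sum(labs == 1) * vox)
    expect_identical(mf$nonplacental_content_volume_mm3, sum(labs == 3) * vox)
  }
})

test_that("in-plane refinement: raw staircase error shrinks monotonically,
           smoothed estimator stays within tolerance", {
  A_true <- 4 * pi * 40^2
  errs <- vapply(c(4.8, 2.4, 1.2), function(dx) {
    geom <- grid_geometry(c(dx, dx, 6), 10)
    n <- round(160 / dx)
    labs <- rasterize_to_slices(ball_label_fun(40), c(n, n, 12), geom)
    raw <- mask_mesh(labs == 1, geom$voxel_size_mm, geom$slice_spacing_mm,
                     smooth_vox = 0)
    sm <- mask_mesh(labs == 1, geom$voxel_size_mm, geom$slice_spacing_mm)
    c(abs(raw$area_mm2 / A_true - 1), abs(sm$area_mm2 / A_true - 1))
  }, numeric(2))
  # without field smoothing the in-plane staircase dominates and refinement
  # reduces the error monotonically; the default (smoothed) estimator sits
  # on the through-plane error floor and just stays within tolerance
  expect_true(all(diff(errs[1, ]) < 0))
  expect_true(all(errs[2, ] < 0.02))
})

test_that("measured sphericity never exceeds 1 + mesh tolerance", {
  geom <- grid_geometry()
  shapes <- list(
    ball_label_fun(40),
    function(x, y, z) ifelse((x / 60)^2 + (y / 30)^2 + (z / 30)^2 < 1, 1L, 0L),
    function(x, y, z) ifelse((x / 75)^2 + (y / 25)^2 + (z / 25)^2 < 1, 1L, 0L))
  for (f in shapes) {
    labs <- rasterize_to_slices(f, c(72, 72, 12), geom)
    mf <- measure_frame(labs, geom, measures = c("volumes", "sphericity"))
    expect_lte(sphericity(mf$placental_volume_mm3,
                          mf$placental_surface_area_mm2), 1.02)
  }
})

test_that("measure_frame validates inputs", {
  geom <- grid_geometry()
  expect_error(measure_frame(array(5L, c(4, 4, 2)), geom), "undeclared label")
  expect_error(measure_frame(array(0L, c(4, 4)), geom), "3D")
  expect_error(measure_frame(array(0L, c(4, 4, 2)), list()), "grid_geometry")
  expect_error(grid_geometry(c(2.4, 2.4, 6), 4), "smaller than")
})

test_that("interface areas match spherical cap-slab closed forms", {
  r <- 78
  cfg <- scenario_config(n_frames = 1, noise_sd_fraction = 0,
                         uterus_semiaxes_mm = c(r, r, r))
  s <- simulate_session(cfg)
  mf <- measure_frame(s$labels[[1]], s$geometry)
  beta <- 60 * pi / 180
  bed_true <- 2 * pi * r^2 * (1 - cos(beta))
  wall_true <- 2 * pi * r^2 * (1 + cos(beta))
  expect_lt(abs(mf$placental_bed_area_mm2 / bed_true - 1), 0.10)
  expect_lt(abs(mf$nonplacental_wall_area_mm2 / wall_true - 1), 0.10)
})
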