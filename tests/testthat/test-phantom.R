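# Phantom generator: closed-form ground truth vs rasterised output.

test_that("zero events, zero noise: all frames identical, volume constant", {
  s <- simulate_session(small_config(n_frames = 5))
  for (i in 2:5) {
    expect_identical(s$labels[[i]], s$labels[[1]])
    expect_identical(s$signal[[i]], s$signal[[1]])
  }
  expect_equal(nrow(s$ground_truth), 0)
})

test_that("single placental event: ground truth and rasterised drop agree", {
  s <- basic_session()   # amplitude 0.2, duration 360 s
  gt <- s$ground_truth
  expect_equal(nrow(gt), 1)
  expect_identical(gt$kind, "placental")
  expect_equal(gt$peak_volume_drop_frac, 0.2)
  expect_equal(gt$halfmax_duration_s, 180)   # raised cosine: duration / 2
  # rasterised volume drop tracks the analytic model within rasterisation
  # tolerance (the analytic state series is the continuous-model oracle)
  v <- vapply(s$labels, function(l) sum(l == 1L), 0)
  expect_lt(abs(min(v) / v[1] - 0.8), 0.02)
  v_analytic <- s$state$v_placenta_mm3
  expect_lt(max(abs(v / v[1] - v_analytic / v_analytic[1])), 0.025)
})

test_that("rng_seed changes signal noise only; same seed is bit-identical", {
  ev <- list(event_spec("placental", 30, 100, 0.15))
  c1 <- small_config(n_frames = 10, events = ev, noise_sd_fraction = 0.02,
                     rng_seed = 1)
  c2 <- small_config(n_frames = 10, events = ev, noise_sd_fraction = 0.02,
                     rng_seed = 2)
  s1 <- simulate_session(c1); s2 <- simulate_session(c2)
  for (i in 1:10) expect_identical(s1$labels[[i]], s2$labels[[i]])
  expect_false(identical(s1$signal[[2]], s2$signal[[2]]))
  s1b <- simulate_session(c1)
  expect_identical(s1$signal, s1b$signal)
  expect_identical(s1$timestamps_s, s1b$timestamps_s)
})

test_that("intra-uterine content volume is conserved within 2%", {
  s <- basic_session()
  vc <- vapply(s$labels, function(l) sum(l == 3L), 0)
  expect_lt(max(abs(vc / vc[1] - 1)), 0.02)
})

test_that("larger amplitude strictly deepens the volume trough", {
  mins <- vapply(c(0.1, 0.2, 0.3), function(a) {
    s <- simulate_session(small_config(
      n_frames = 25, events = list(event_spec("placental", 90, 180, a))))
    min(vapply(s$labels, function(l) sum(l == 1L), 0))
  }, 0)
  expect_true(all(diff(mins) < 0))
})

test_that("sign structure: placental events raise sphericity and free wall
           area, uterine events lower sphericity", {
  s <- basic_session()
  peak <- which.min(s$state$v_placenta_mm3)
  at <- function(i) measure_frame(s$labels[[i]], s$geometry)
  m0 <- at(1); m1 <- at(peak)
  psi0 <- sphericity(m0$placental_volume_mm3, m0$placental_surface_area_mm2)
  psi1 <- sphericity(m1$placental_volume_mm3, m1$placental_surface_area_mm2)
  expect_gt(psi1, psi0)
  expect_gt(m1$nonplacental_wall_area_mm2, m0$nonplacental_wall_area_mm2)

  su <- cached("uterine_session", function() simulate_session(
    scenario_config(n_frames = 40, noise_sd_fraction = 0,
                    events = list(event_spec("uterine_uniform", 150, 300,
                                             0.15)))))
  peak_u <- which.min(su$state$v_placenta_mm3)
  mu0 <- measure_frame(su$labels[[1]], su$geometry)
  mu1 <- measure_frame(su$labels[[peak_u]], su$geometry)
  expect_lte(
    sphericity(mu1$placental_volume_mm3, mu1$placental_surface_area_mm2),
    sphericity(mu0$placental_volume_mm3, mu0$placental_surface_area_mm2))
})

test_that("scenario validation rejects invalid worlds", {
  expect_error(event_spec("placental", 0, 100, 0.7), "amplitude")
  expect_error(event_spec("placental", 0, -5, 0.2), "duration")
  expect_error(event_spec("placental", 0, 100, 0.2, sphericity_delta = -0.01),
               "sphericity_delta > 0")
  expect_error(event_spec("uterine_local", 0, 100, 0.2,
                          sphericity_delta = 0.01), "sphericity_delta <= 0")
  expect_error(small_config(30, events = list(
    event_spec("placental", 0, 200, 0.2),
    event_spec("placental", 100, 200, 0.2))), "overlapping")
  # different kinds may overlap
  expect_s3_class(small_config(30, events = list(
    event_spec("placental", 0, 200, 0.2),
    event_spec("uterine_uniform", 100, 200, 0.2))), "uterodyn_scenario")
  expect_error(small_config(4, events = list(
    event_spec("placental", 0, 2000, 0.2))), "outside the session")
  expect_error(scenario_config(wall_thickness_mm = 1), "too coarse")
  expect_error(scenario_config(placenta_cap_angle_deg = 190), "cap_angle")
  expect_error(scenario_config(slice_spacing_mm = 3), "slice thickness")
  expect_error(small_config(5, motion_events = list(
    list(frame = 99, type = "maternal"))), "out of range")
})

test_that("rasterize_to_slices: empty model and aligned half-space", {
  geom <- grid_geometry(c(4.8, 4.8, 6), 15)
  empty <- rasterize_to_slices(function(x, y, z) rep(0L, length(x)),
                               c(12, 12, 6), geom)
  expect_true(all(empty == 0L))
  # slice centres at -37.5 ... 37.5: the z < 0 half-space fills slices 1:3
  hs <- rasterize_to_slices(function(x, y, z) ifelse(z < 0, 1L, 0L),
                            c(12, 12, 6), geom)
  expect_true(all(hs[, , 1:3] == 1L))
  expect_true(all(hs[, , 4:6] == 0L))
})

test_that("cap-state solver honours volume and sphericity targets", {
  st0 <- solve_cap_state(1, cap_slab_volume(1, 0.68, 1.0),
                         cap_slab_sphericity(1, 0.68, 1.0))
  expect_equal(st0$beta, 1.0, tolerance = 1e-6)
  expect_equal(st0$ri, 0.68, tolerance = 1e-6)
  # perturbed targets are met exactly
  v_t <- cap_slab_volume(1, 0.68, 1.0) * 0.8
  psi_t <- cap_slab_sphericity(1, 0.68, 1.0) + 0.012
  st <- solve_cap_state(0.99, v_t, psi_t)
  expect_equal(cap_slab_volume(st$rc, st$ri, st$beta), v_t, tolerance = 1e-8)
  expect_equal(cap_slab_sphericity(st$rc, st$ri, st$beta), psi_t,
               tolerance = 1e-6)
})
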