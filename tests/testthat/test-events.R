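# Event detection, baselines, half-max durations and features on synthetic
# series with known geometry (unit tests) and phantom ground truth.

# regular-sampling helper series: flat at 100 with a raised-cosine dip
dip_series <- function(n, dt, onset, dur, amp_pct) {
  t <- (seq_len(n) - 1) * dt
  x <- (t - onset) / dur
  f <- ifelse(x > 0 & x < 1, 0.5 * (1 - cos(2 * pi * x)), 0)
  list(t = t, v = 100 - amp_pct * f)
}

test_that("no events on constant or single-frame-dip series", {
  t <- (0:29) * 15
  expect_equal(nrow(detect_events(rep(100, 30), t)), 0)
  v <- rep(100, 30); v[15] <- 80
  expect_equal(nrow(detect_events(v, t, min_consecutive = 2)), 0)
  expect_equal(nrow(detect_events(v, t, min_consecutive = 1)), 1)
})

test_that("three separated dips are detected with correct onsets", {
  d <- dip_series(120, 15, 300, 240, 15)
  d2 <- dip_series(120, 15, 800, 240, 20)
  d3 <- dip_series(120, 15, 1300, 240, 12)
  v <- pmin(d$v, d2$v, d3$v)
  ev <- detect_events(v, d$t)
  expect_equal(nrow(ev), 3)
  # first below-threshold frame lies inside each event window
  expect_true(all(d$t[ev$start_index] > c(300, 800, 1300)))
  expect_true(all(d$t[ev$end_index] < c(540, 1040, 1540)))
  expect_false(any(ev$truncated_start | ev$truncated_end))
})

test_that("nearby dips merge within merge_gap_frames", {
  d1 <- dip_series(60, 15, 200, 120, 20)
  d2 <- dip_series(60, 15, 350, 120, 20)
  v <- pmin(d1$v, d2$v)
  ev2 <- detect_events(v, d1$t, merge_gap_frames = 3)
  ev0 <- detect_events(v, d1$t, merge_gap_frames = 0)
  expect_lte(nrow(ev2), nrow(ev0))
})

test_that("series starting below rest is flagged truncated", {
  d <- dip_series(40, 15, -100, 300, 25)
  ev <- detect_events(d$v, d$t)
  expect_gte(nrow(ev), 1)
  expect_true(ev$truncated_start[1])
  expect_true(is.na(ev$pre_rest_index[1]))
})

test_that("no-rest series degenerates to one truncated event", {
  v <- c(100, 60.1, 55.3, 54.2, 58.7, 57.1, 53.9)
  expect_warning(ev <- detect_events(v, (0:6) * 15, rest_tolerance = 1e-4),
                 "no rest")
  expect_equal(nrow(ev), 1)
  expect_true(ev$truncated_start & ev$truncated_end)
})

test_that("local baseline: linear in time, constant when truncated", {
  ev <- list(start_index = 2L, end_index = 4L, pre_rest_index = 1L,
             post_rest_index = 5L)
  t <- c(0, 50, 100, 150, 200)
  series <- c(100, 97, 92, 94, 90)
  bl <- local_baseline(ev, series, t)
  expect_equal(bl$baseline[t[bl$indices] == 100], 95)   # midpoint
  ev$post_rest_index <- NA_integer_
  bl2 <- local_baseline(ev, series, t)
  expect_true(all(bl2$baseline == 100))
  ev$pre_rest_index <- NA_integer_
  expect_warning(bl3 <- local_baseline(ev, series, t), "global_rest_value")
  bl4 <- local_baseline(ev, series, t, global_rest_value = 99)
  expect_true(all(bl4$baseline == 99))
})

test_that("half-max duration: triangle closed form and truncation flag", {
  # symmetric triangular dip, base 240 s -> half-max width exactly 120 s
  t <- (0:40) * 10
  v <- rep(100, 41)
  ramp <- seq(0, 20, length.out = 13)
  v[10:22] <- 100 - ramp
  v[22:34] <- 100 - rev(ramp)
  ev <- list(start_index = 12L, end_index = 32L, pre_rest_index = 10L,
             post_rest_index = 34L)
  bl <- local_baseline(ev, v, t)
  hm <- halfmax_duration(ev, v, t, bl)
  expect_equal(hm$minutes, 2, tolerance = 1e-9)
  expect_false(hm$lower_bound)
  # truncated falling flank: deviation never returns below half max
  vt <- v[1:25]; tt <- t[1:25]
  evt <- list(start_index = 12L, end_index = 25L, pre_rest_index = 10L,
              post_rest_index = NA_integer_)
  blt <- local_baseline(evt, vt, tt)
  hmt <- halfmax_duration(evt, vt, tt, blt)
  expect_true(hmt$lower_bound)
})

test_that("half-max duration scales exactly with time rescaling", {
  d <- dip_series(80, 15, 300, 300, 20)
  ev <- detect_events(d$v, d$t)
  bl <- local_baseline(ev[1, ], d$v, d$t)
  h1 <- halfmax_duration(ev[1, ], d$v, d$t, bl)
  bl2 <- local_baseline(ev[1, ], d$v, d$t * 3)
  h2 <- halfmax_duration(ev[1, ], d$v, d$t * 3, bl2)
  expect_equal(h2$minutes / h1$minutes, 3, tolerance = 1e-9)
})

test_that("max drop is invariant to an added linear trend", {
  d <- dip_series(100, 15, 400, 300, 18)
  trend <- 0.004 * d$t
  e1 <- detect_events(d$v, d$t)
  e2 <- detect_events(d$v + trend, d$t)
  expect_equal(nrow(e1), 1); expect_equal(nrow(e2), 1)
  drop_of <- function(ev, v) {
    bl <- local_baseline(ev[1, ], v, d$t)
    max(bl$baseline - v[bl$indices])
  }
  expect_equal(drop_of(e2, d$v + trend), drop_of(e1, d$v), tolerance = 0.15)
})

test_that("event features on the phantom match ground truth", {
  s <- basic_session()
  tc <- cached("basic_tc", function()
    build_timecourse(s, measures = c("volumes", "sphericity")))
  ev <- detect_events(tc$v_placenta_pct, tc$timestamp_s)
  expect_equal(nrow(ev), 1)
  fe <- event_features(ev, tc)
  expect_lt(abs(fe$max_volume_drop_pct - 20), 1.5)
  expect_lt(abs(fe$halfmax_duration_min - 3) * 60, 20)
  expect_gt(fe$max_sphericity_change, 0.005)
  expect_gt(fe$dr2s_change_per_ms, 0.001)
  expect_false(fe$motion_affected)
})

test_that("zero-amplitude pseudo-event yields zero features", {
  t <- (0:19) * 15
  v <- rep(100, 20)
  ev <- data.frame(start_index = 8L, end_index = 12L, pre_rest_index = 6L,
                   post_rest_index = 14L, truncated_start = FALSE,
                   truncated_end = FALSE)
  tc <- structure(
    data.frame(timestamp_s = t, v_placenta_pct = v, a_wall_pct = v,
               sphericity = rep(0.64, 20), dr2s_per_ms = rep(0, 20)),
    baseline_index = 1L, class = c("uterodyn_timecourse", "data.frame"))
  fe <- event_features(ev, tc)
  expect_equal(fe$max_volume_drop_pct, 0)
  expect_equal(fe$max_wall_area_change_pct, 0)
  expect_equal(fe$max_sphericity_change, 0)
  expect_equal(fe$dr2s_change_per_ms, 0)
  expect_true(is.na(fe$halfmax_duration_min))
})

test_that("contraction rate arithmetic", {
  expect_equal(contraction_rate(3, 1800), 6)
  expect_equal(contraction_rate(0, 1800), 0)
  expect_equal(contraction_rate(2, 32 * 60), 3.75)
  expect_error(contraction_rate(1, 0), "positive")
})
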