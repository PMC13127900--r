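# Shared phantom fixtures. Sessions are generated in code (no stored data)
# and cached per test run because simulation is the expensive step.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .phantom_cache))
    assign(name, maker(), envir = .phantom_cache)
  get(name, envir = .phantom_cache)
}

# A 30-minute session with randomly placed non-overlapping contraction
# events, emulating the acquisition this package targets. Event durations
# are drawn from the upper range of observed complete contraction lengths
# (5-8 min) so that the 15 s mean sampling and the 5-point smoother resolve
# the peaks; amplitudes span 0.12-0.30.
random_scenario <- function(seed, n_frames = 120, noise_sd_fraction = 0.02,
                            amp_range = c(0.12, 0.30),
                            dur_range = c(300, 480),
                            kinds = c("placental", "uterine_uniform",
                                      "uterine_local"),
                            max_events = 4) {
  uterodyn:::with_seed(seed, {
    events <- list()
    t0 <- runif(1, 120, 200)
    n_target <- sample(seq_len(max_events), 1)
    for (k in seq_len(n_target)) {
      dur <- runif(1, dur_range[1], dur_range[2])
      if (t0 + dur > 1500) break
      kind <- sample(kinds, 1)
      events[[length(events) + 1]] <-
        event_spec(kind, onset_s = t0, duration_s = dur,
                   amplitude = runif(1, amp_range[1], amp_range[2]))
      t0 <- t0 + dur + runif(1, 150, 250)
    }
    scenario_config(n_frames = n_frames,
                    noise_sd_fraction = noise_sd_fraction,
                    events = events,
                    rng_seed = seed, timing_seed = seed + 1000L)
  })
}

# match detected events to ground truth by interval overlap
match_events <- function(detected, timestamps_s, gt) {
  if (!nrow(detected) || !nrow(gt))
    return(list(matched_gt = integer(0), matched_det = integer(0)))
  det_on <- timestamps_s[detected$start_index]
  det_off <- timestamps_s[detected$end_index]
  matched_gt <- integer(0); matched_det <- integer(0)
  for (g in seq_len(nrow(gt))) {
    ov <- which(det_on <= gt$offset_s[g] & det_off >= gt$onset_s[g])
    ov <- setdiff(ov, matched_det)
    if (length(ov)) {
      matched_gt <- c(matched_gt, g)
      matched_det <- c(matched_det, ov[1])
    }
  }
  list(matched_gt = matched_gt, matched_det = matched_det)
}

# coarse grid for cheap unit tests (4.8 mm in-plane, 15 mm spacing)
small_config <- function(n_frames, events = list(), noise_sd_fraction = 0,
                         ...) {
  scenario_config(grid_shape = c(48, 48, 16),
                  voxel_size_mm = c(4.8, 4.8, 6), slice_spacing_mm = 15,
                  n_frames = n_frames, events = events,
                  noise_sd_fraction = noise_sd_fraction, ...)
}

# small, fast default session shared by several test files
basic_session <- function() {
  cached("basic_session", function() {
    cfg <- scenario_config(
      n_frames = 60, noise_sd_fraction = 0,
      events = list(event_spec("placental", onset_s = 200, duration_s = 360,
                               amplitude = 0.2)))
    simulate_session(cfg)
  })
}
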