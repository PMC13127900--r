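# Contraction-event detection and per-event feature extraction.
#
# Detection is automatic (the measurement pipeline needs reproducible events,
# not rater consensus): rest frames are found iteratively, the rest
# reference is interpolated across gaps, and events are maximal runs of
# frames falling more than a threshold below it.

#' Detect contraction events on a placental-volume series
#'
#' Rest frames are frames within `rest_tolerance` % of the running rest
#' reference (median of rest frames, iterated to convergence). The reference
#' is linearly interpolated in time across non-rest stretches; candidate
#' events are maximal runs of at least `min_consecutive` frames falling more
#' than `drop_threshold_pct` % below it. Candidates separated by at most
#' `merge_gap_frames` frames are merged. Events touching the first/last
#' frame, or lacking a flanking rest frame, are flagged truncated.
#'
#' @param v_pct smoothed placental-volume series, % of earliest rest
#'   (a raw-unit series also works: thresholds are relative).
#' @param timestamps_s frame times, seconds, strictly increasing.
#' @param drop_threshold_pct detection threshold, % below the reference.
#' @param min_consecutive minimum run length, frames.
#' @param merge_gap_frames maximum gap merged between candidate runs.
#' @param rest_tolerance rest tolerance, % of the rest reference.
#' @param anchor_pad_frames flanking rest anchors are stepped this many
#'   frames further into their rest segment (when possible), so that the
#'   moving-average window of the anchor value does not overlap contraction
#'   frames; default half the 5-point smoothing span. Set 0 to anchor at the
#'   rest frame immediately adjacent to the event.
#' @return data.frame of class `uterodyn_candidates` with columns
#'   `start_index`, `end_index`, `pre_rest_index`, `post_rest_index`,
#'   `truncated_start`, `truncated_end`; attributes `rest` (logical per
#'   frame) and `rest_reference` (interpolated reference series).
#' @export
detect_events <- function(v_pct, timestamps_s,
                          drop_threshold_pct = 5, min_consecutive = 2,
                          merge_gap_frames = 2, rest_tolerance = 2,
                          anchor_pad_frames = 2) {
  n <- length(v_pct)
  stopifnot(n == length(timestamps_s), n >= 1)
  if (n >= 2 && any(diff(timestamps_s) <= 0))
    stop("detect_events: timestamps must be strictly increasing")
  r <- .find_rest_frames(v_pct, rest_tolerance)
  empty <- data.frame(start_index = integer(0), end_index = integer(0),
                      pre_rest_index = integer(0),
                      post_rest_index = integer(0),
                      truncated_start = logical(0),
                      truncated_end = logical(0))
  if (!any(r$rest)) {
    warning("detect_events: no rest segment; whole series is one truncated event")
    out <- data.frame(start_index = 1L, end_index = n,
                      pre_rest_index = NA_integer_,
                      post_rest_index = NA_integer_,
                      truncated_start = TRUE, truncated_end = TRUE)
    return(structure(out, rest = r$rest,
                     rest_reference = rep(r$ref, n),
                     class = c("uterodyn_candidates", "data.frame")))
  }
  ref_t <- approx(timestamps_s[r$rest], v_pct[r$rest], xout = timestamps_s,
                  rule = 2)$y
  below <- v_pct < ref_t * (1 - drop_threshold_pct / 100)
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_consecutive
  if (!any(keep)) {
    return(structure(empty, rest = r$rest, rest_reference = ref_t,
                     class = c("uterodyn_candidates", "data.frame")))
  }
  st <- starts[keep]; en <- ends[keep]
  # merge candidates separated by short gaps
  ms <- st[1]; me <- en[1]; outs <- integer(0); oute <- integer(0)
  if (length(st) > 1) {
    for (i in 2:length(st)) {
      if (st[i] - me - 1L <= merge_gap_frames) me <- en[i]
      else { outs <- c(outs, ms); oute <- c(oute, me); ms <- st[i]; me <- en[i] }
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  rest_idx <- which(r$rest)
  pre <- vapply(outs, function(s) {
    p <- rest_idx[rest_idx < s]
    if (!length(p)) return(NA_integer_)
    a <- max(p)
    for (k in seq_len(anchor_pad_frames))
      if ((a - 1L) %in% rest_idx) a <- a - 1L
    a
  }, integer(1))
  post <- vapply(oute, function(e) {
    p <- rest_idx[rest_idx > e]
    if (!length(p)) return(NA_integer_)
    a <- min(p)
    for (k in seq_len(anchor_pad_frames))
      if ((a + 1L) %in% rest_idx) a <- a + 1L
    a
  }, integer(1))
  out <- data.frame(start_index = outs, end_index = oute,
                    pre_rest_index = pre, post_rest_index = post,
                    truncated_start = is.na(pre) | outs == 1L,
                    truncated_end = is.na(post) | oute == n)
  structure(out, rest = r$rest, rest_reference = ref_t,
            class = c("uterodyn_candidates", "data.frame"))
}

#' Local baseline for one event
#'
#' The baseline is linear in time between the series value at the last rest
#' frame before the event and the first rest frame after it. On a truncated
#' side the baseline is constant at the value from the available side; with
#' both sides truncated it is constant at `global_rest_value`.
#'
#' @param event one-row slice of a [detect_events()] result (or a list with
#'   the same fields).
#' @param series numeric series (same frames as detection).
#' @param timestamps_s frame times, seconds.
#' @param global_rest_value fallback baseline level for fully truncated
#'   events (typically the series value at the global earliest rest).
#' @return list with `indices` (frame window from the pre-rest to the
#'   post-rest frame, clipped to the scan) and `baseline` (values over that
#'   window).
#' @export
local_baseline <- function(event, series, timestamps_s,
                           global_rest_value = NULL) {
  n <- length(series)
  i0 <- if (!is.na(event$pre_rest_index)) event$pre_rest_index
        else event$start_index
  i1 <- if (!is.na(event$post_rest_index)) event$post_rest_index
        else event$end_index
  w <- i0:i1
  tw <- timestamps_s[w]
  if (!is.na(event$pre_rest_index) && !is.na(event$post_rest_index)) {
    y0 <- series[event$pre_rest_index]; y1 <- series[event$post_rest_index]
    t0 <- timestamps_s[event$pre_rest_index]
    t1 <- timestamps_s[event$post_rest_index]
    bl <- y0 + (y1 - y0) * (tw - t0) / (t1 - t0)
  } else if (!is.na(event$pre_rest_index)) {
    bl <- rep(series[event$pre_rest_index], length(w))
  } else if (!is.na(event$post_rest_index)) {
    bl <- rep(series[event$post_rest_index], length(w))
  } else {
    if (is.null(global_rest_value)) {
      warning("local_baseline: event truncated on both sides and no ",
              "global_rest_value given; using series median")
      global_rest_value <- median(series)
    }
    bl <- rep(global_rest_value, length(w))
  }
  list(indices = w, baseline = bl)
}

#' Half-maximum duration of an event
#'
#' The deviation is `baseline - series` over the event window; the duration
#' is the time between the two crossings of half the maximum deviation,
#' located by linear interpolation between the adjacent (irregular) frame
#' times on the rising and falling flanks.
#'
#' @param event one-row event (see [local_baseline()]).
#' @param series the series defining the deviation (placental volume).
#' @param timestamps_s frame times, seconds.
#' @param baseline result of [local_baseline()] for this event/series.
#' @return list with `minutes` and `lower_bound` (TRUE when a flank never
#'   drops below half maximum, e.g. for scan-truncated events, so the value
#'   is a lower bound).
#' @export
halfmax_duration <- function(event, series, timestamps_s, baseline) {
  w <- baseline$indices
  d <- baseline$baseline - series[w]
  dmax <- max(d)
  if (!(dmax > 0)) stop("halfmax_duration: event has no positive deviation")
  half <- dmax / 2
  peak <- which.max(d)   # first attaining frame on a plateau
  tw <- timestamps_s[w]
  lower_bound <- FALSE
  cross <- function(i, j) {
    # linear interpolation of the half crossing between frames i < j
    tw[i] + (half - d[i]) / (d[j] - d[i]) * (tw[j] - tw[i])
  }
  before <- which(d[seq_len(peak)] < half)
  if (length(before)) {
    i <- max(before)
    t_rise <- cross(i, i + 1)
  } else { t_rise <- tw[1]; lower_bound <- TRUE }
  after <- which(d[peak:length(d)] < half)
  if (length(after)) {
    j <- peak + min(after) - 1L
    t_fall <- cross(j, j - 1)
  } else { t_fall <- tw[length(tw)]; lower_bound <- TRUE }
  list(minutes = (t_fall - t_rise) / 60, lower_bound = lower_bound)
}

#' Complete per-event features
#'
#' Builds, for every candidate event, a local baseline per series (same rule
#' for volumes, areas and sphericity), then fills the half-maximum duration,
#' the maximum % placental-volume drop (positive for a decrease; read from
#' the raw volume series against the smoothed baseline, since the moving
#' average attenuates single peaks), the signed
#' extreme % change of the non-placental wall area, the signed extreme
#' sphericity change, and the delta-R2* change read at the frame of maximum
#' volume deviation (avoiding noise-maximum bias; set
#' `dr2s_mode = "extremum"` for the signed extreme instead).
#'
#' @param candidates result of [detect_events()].
#' @param tc a `uterodyn_timecourse`.
#' @param dr2s_mode `"at_volume_peak"` (default) or `"extremum"`.
#' @param motion optional result of [motion_trace()]; events containing a
#'   frame whose maternal or fetal movement exceeds `motion_spike_pct` are
#'   flagged `motion_affected`.
#' @param motion_spike_pct per-frame movement spike threshold, %.
#' @return data.frame of class `uterodyn_events`: the candidate columns plus
#'   `halfmax_duration_min`, `halfmax_lower_bound`, `max_volume_drop_pct`,
#'   `max_wall_area_change_pct`, `max_sphericity_change`,
#'   `dr2s_change_per_ms`, `motion_affected`.
#' @export
event_features <- function(candidates, tc, dr2s_mode = "at_volume_peak",
                           motion = NULL, motion_spike_pct = 10) {
  dr2s_mode <- match.arg(dr2s_mode, c("at_volume_peak", "extremum"))
  ts <- tc$timestamp_s
  bi <- attr(tc, "baseline_index")
  out <- as.data.frame(candidates)
  ne <- nrow(out)
  out$halfmax_duration_min <- rep(NA_real_, ne)
  out$halfmax_lower_bound <- rep(FALSE, ne)
  out$max_volume_drop_pct <- rep(NA_real_, ne)
  out$max_wall_area_change_pct <- rep(NA_real_, ne)
  out$max_sphericity_change <- rep(NA_real_, ne)
  out$dr2s_change_per_ms <- rep(NA_real_, ne)
  out$motion_affected <- rep(FALSE, ne)
  signed_extreme <- function(dev) dev[which.max(abs(dev))]
  # the smoothed series defines baselines, peaks and durations; the drop
  # extremum is read from the raw series (when available) because the
  # 5-point average attenuates single peaks by up to ~10% relative at the
  # 15 s sampling of the target acquisition
  v_raw <- tc$v_placenta_raw_pct %||% tc$v_placenta_pct
  for (i in seq_len(ne)) {
    ev <- out[i, ]
    blv <- local_baseline(ev, tc$v_placenta_pct, ts,
                          global_rest_value = tc$v_placenta_pct[bi])
    dv <- blv$baseline - tc$v_placenta_pct[blv$indices]
    out$max_volume_drop_pct[i] <- max(blv$baseline - v_raw[blv$indices])
    if (max(dv) > 0) {
      hm <- halfmax_duration(ev, tc$v_placenta_pct, ts, blv)
      out$halfmax_duration_min[i] <- hm$minutes
      out$halfmax_lower_bound[i] <- hm$lower_bound
    }
    if (!all(is.na(tc$a_wall_pct))) {
      blw <- local_baseline(ev, tc$a_wall_pct, ts, tc$a_wall_pct[bi])
      out$max_wall_area_change_pct[i] <-
        signed_extreme(tc$a_wall_pct[blw$indices] - blw$baseline)
    }
    if (!all(is.na(tc$sphericity))) {
      bls <- local_baseline(ev, tc$sphericity, ts, tc$sphericity[bi])
      out$max_sphericity_change[i] <-
        signed_extreme(tc$sphericity[bls$indices] - bls$baseline)
    }
    blr <- local_baseline(ev, tc$dr2s_per_ms, ts, tc$dr2s_per_ms[bi])
    dr <- tc$dr2s_per_ms[blr$indices] - blr$baseline
    out$dr2s_change_per_ms[i] <- if (dr2s_mode == "extremum")
      signed_extreme(dr) else dr[which.max(dv)]
    if (!is.null(motion)) {
      w <- ev$start_index:ev$end_index
      spike <- pmax(motion$maternal_pct[w], motion$fetal_pct[w])
      out$motion_affected[i] <- any(spike > motion_spike_pct)
    }
  }
  class(out) <- c("uterodyn_events", "data.frame")
  out
}

#' Contractions per hour
#'
#' @param n_events number of detected events.
#' @param session_duration_s acquisition duration, seconds (> 0).
#' @return events per hour.
#' @examples
#' contraction_rate(3, 1800)  # 6 per hour
#' @export
contraction_rate <- function(n_events, session_duration_s) {
  if (!(session_duration_s > 0))
    stop("contraction_rate: session duration must be positive")
  3600 * n_events / session_duration_s
}
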