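# Time-course assembly: smoothing, rest-baseline identification, percent
# normalisation and delta-R2*.

#' Moving-average smoothing with a 5-point span
#'
#' Centred moving average over sample indices (not time: the acquisition is
#' respiratory-triggered and irregular, and the span is defined in time
#' points). At the edges the window shrinks symmetrically, so the first and
#' last points are untouched and the second points average 3 samples.
#'
#' @param x numeric series.
#' @param span odd window length (>= 1).
#' @return smoothed series, same length.
#' @examples
#' smooth_series(c(0, 0, 0, 5, 0, 0, 0), span = 5)  # 0 0 1 1 1 0 0
#' @export
smooth_series <- function(x, span = 5) {
  if (span %% 2 == 0) stop("smooth_series: span must be odd")
  if (span < 1) stop("smooth_series: span must be >= 1")
  n <- length(x)
  if (n == 0) return(x)
  half <- (span - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(half, i - 1, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  out
}

#' Change in R2* from single-echo signal
#'
#' \eqn{\Delta R_2^*(t) = -\frac{1}{TE}\ln(S(t)/S_b)} in ms^-1, where `S(t)`
#' is the mean placental signal at each dynamic and `Sb` its value at the
#' earliest rest volume. A signal drop (more deoxygenated blood, less inflow)
#' gives a positive delta.
#'
#' @param s_mean numeric vector of mean placental signal, arbitrary units.
#' @param sb baseline signal (positive scalar).
#' @param te_ms echo time, ms.
#' @return delta-R2* series, ms^-1.
#' @examples
#' delta_r2star(exp(-1), 1, 25)  # 0.04 ms^-1
#' @export
delta_r2star <- function(s_mean, sb, te_ms) {
  if (!is.numeric(te_ms) || te_ms <= 0) stop("delta_r2star: te_ms must be > 0")
  if (!is.numeric(sb) || length(sb) != 1 || sb <= 0)
    stop("delta_r2star: Sb must be a positive scalar")
  bad <- which(!is.finite(s_mean) | s_mean <= 0)
  if (length(bad))
    stop("delta_r2star: nonpositive signal at frame(s) ",
         paste(head(bad, 5), collapse = ", "))
  -log(s_mean / sb) / te_ms
}

# Iterative rest-frame identification: frames within rest_tolerance (%) of
# the running rest reference (median of currently-flagged rest frames).
# Contractions are dips, so the reference converges onto the resting level.
.find_rest_frames <- function(series, rest_tolerance = 2) {
  n <- length(series)
  if (n == 1) return(list(rest = TRUE, ref = series))
  ref <- quantile(series, 0.75, names = FALSE)
  rest <- rep(TRUE, n)
  for (it in 1:20) {
    new_rest <- abs(series - ref) <= rest_tolerance / 100 * abs(ref)
    if (!any(new_rest)) { rest <- new_rest; break }
    new_ref <- median(series[new_rest])
    if (identical(new_rest, rest) && isTRUE(all.equal(new_ref, ref))) break
    rest <- new_rest; ref <- new_ref
  }
  list(rest = rest, ref = ref)
}

#' Earliest rest volume of a series
#'
#' Index (1-based) of the first frame belonging to a rest segment of the
#' placental-volume series. If acquisition started during a contraction this
#' is the first frame after release, not frame 1.
#'
#' @param v_placenta numeric (ideally smoothed) placental volume series.
#' @param rest_tolerance rest tolerance as % of the running rest reference.
#' @return integer index.
#' @export
find_earliest_rest <- function(v_placenta, rest_tolerance = 2) {
  if (!length(v_placenta)) stop("find_earliest_rest: empty series")
  r <- .find_rest_frames(v_placenta, rest_tolerance)
  idx <- which(r$rest)
  if (!length(idx))
    stop("find_earliest_rest: no rest segment found; supply a baseline ",
         "index manually")
  idx[1]
}

#' Assemble an analysis-ready time course from a dynamic session
#'
#' Measures every frame ([measure_frame()]), extracts the mean placental
#' signal with the per-frame placenta mask, smooths all series with a
#' 5-point moving average, anchors the baseline at the earliest rest volume,
#' normalises volumes and areas to percent of their earliest-rest values and
#' computes delta-R2*.
#'
#' @param session a `uterodyn_session` (from [simulate_session()] or
#'   [read_session()]).
#' @param measures passed to [measure_frame()]; drop `"surfaces"` for a fast
#'   volume-only time course (sphericity and area columns become `NA`).
#' @param span smoothing span (odd), default 5 time points.
#' @param rest_tolerance rest tolerance, % of the running rest reference.
#' @param baseline_index override for the earliest-rest index (required if
#'   no rest segment can be found automatically).
#' @param iso_dz passed to [measure_frame()].
#' @return a `data.frame` of class `uterodyn_timecourse` with one row per
#'   frame: `timestamp_s`, smoothed measurements, percent-of-rest series
#'   (`*_pct`), `v_placenta_raw_pct` (unsmoothed volume as % of the rest
#'   level, used for drop extrema), `sphericity`, `s_mean` and
#'   `dr2s_per_ms`. Attributes: `baseline_index`, `sb`, `te_ms`, `span`,
#'   `raw` (unsmoothed measurement table).
#' @export
build_timecourse <- function(session, measures = c("volumes", "surfaces"),
                             span = 5, rest_tolerance = 2,
                             baseline_index = NULL, iso_dz = NULL) {
  n <- length(session$timestamps_s)
  rows <- vector("list", n)
  s_mean <- numeric(n)
  for (i in seq_len(n)) {
    rows[[i]] <- measure_frame(session$labels[[i]], session$geometry,
                               timestamp_s = session$timestamps_s[i],
                               measures = measures, iso_dz = iso_dz)
    pm <- session$labels[[i]] == LBL_PLACENTA
    s_mean[i] <- if (any(pm)) mean(session$signal[[i]][pm]) else NA_real_
  }
  m <- do.call(rbind, rows)
  tc <- data.frame(
    timestamp_s = m$timestamp_s,
    v_placenta_mm3 = smooth_series(m$placental_volume_mm3, span),
    v_content_mm3 = smooth_series(m$nonplacental_content_volume_mm3, span),
    a_surface_mm2 = if (all(is.na(m$placental_surface_area_mm2))) NA_real_
      else smooth_series(m$placental_surface_area_mm2, span),
    a_bed_mm2 = if (all(is.na(m$placental_bed_area_mm2))) NA_real_
      else smooth_series(m$placental_bed_area_mm2, span),
    a_wall_mm2 = if (all(is.na(m$nonplacental_wall_area_mm2))) NA_real_
      else smooth_series(m$nonplacental_wall_area_mm2, span),
    s_mean = smooth_series(s_mean, span))
  tc$sphericity <- if (all(is.na(tc$a_surface_mm2))) NA_real_
    else sphericity(tc$v_placenta_mm3, tc$a_surface_mm2)

  if (is.null(baseline_index))
    baseline_index <- find_earliest_rest(tc$v_placenta_mm3, rest_tolerance)
  sb <- tc$s_mean[baseline_index]
  tc$dr2s_per_ms <- delta_r2star(tc$s_mean, sb, session$te_ms)

  pct <- function(x) 100 * x / x[baseline_index]
  tc$v_placenta_pct <- pct(tc$v_placenta_mm3)
  # raw volume as % of the smoothed rest level: used for the drop extremum,
  # which the moving average would otherwise attenuate
  tc$v_placenta_raw_pct <-
    100 * m$placental_volume_mm3 / tc$v_placenta_mm3[baseline_index]
  tc$v_content_pct <- pct(tc$v_content_mm3)
  tc$a_surface_pct <- if (all(is.na(tc$a_surface_mm2))) NA_real_
    else pct(tc$a_surface_mm2)
  tc$a_bed_pct <- if (all(is.na(tc$a_bed_mm2))) NA_real_
    else pct(tc$a_bed_mm2)
  tc$a_wall_pct <- if (all(is.na(tc$a_wall_mm2))) NA_real_
    else pct(tc$a_wall_mm2)

  structure(tc, baseline_index = baseline_index, sb = sb,
            te_ms = session$te_ms, span = span, raw = m,
            class = c("uterodyn_timecourse", "data.frame"))
}

#' Write a time course to CSV
#' @param tc a `uterodyn_timecourse`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}
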