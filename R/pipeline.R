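# End-to-end convenience wrapper: session -> time course -> events ->
# motion screen -> classification.

#' Analyse one dynamic session end to end
#'
#' @param session a `uterodyn_session`.
#' @param measures passed to [build_timecourse()].
#' @param span smoothing span.
#' @param detection list of [detect_events()] parameters
#'   (`drop_threshold_pct`, `min_consecutive`, `merge_gap_frames`,
#'   `rest_tolerance`).
#' @param classification list of [classify_events()] parameters
#'   (`volume_gate_pct`, `sphericity_threshold`, `use_wall_area`,
#'   `wall_area_threshold_pct`).
#' @param motion logical: run the motion screen.
#' @param iso_dz passed to [measure_frame()].
#' @return list of class `uterodyn_analysis` with `timecourse`, `events`
#'   (classified), `motion`, `summary` ([classify_session()] output) and
#'   `duration_s`.
#' @export
analyze_session <- function(session, measures = c("volumes", "surfaces"),
                            span = 5,
                            detection = list(), classification = list(),
                            motion = TRUE, iso_dz = NULL) {
  tc <- build_timecourse(session, measures = measures, span = span,
                         rest_tolerance = detection$rest_tolerance %||% 2,
                         iso_dz = iso_dz)
  cand <- detect_events(
    tc$v_placenta_pct, tc$timestamp_s,
    drop_threshold_pct = detection$drop_threshold_pct %||% 5,
    min_consecutive = detection$min_consecutive %||% 2,
    merge_gap_frames = detection$merge_gap_frames %||% 2,
    rest_tolerance = detection$rest_tolerance %||% 2,
    anchor_pad_frames = detection$anchor_pad_frames %||% 2)
  mot <- if (motion) motion_trace(session, cand) else NULL
  ev <- event_features(cand, tc, motion = mot)
  cl <- classify_events(
    ev,
    volume_gate_pct = classification$volume_gate_pct %||% 10,
    sphericity_threshold = classification$sphericity_threshold %||% 0.005,
    use_wall_area = classification$use_wall_area %||% FALSE,
    wall_area_threshold_pct = classification$wall_area_threshold_pct)
  dur <- max(tc$timestamp_s) - min(tc$timestamp_s)
  structure(list(timecourse = tc, events = cl, motion = mot,
                 summary = classify_session(cl, dur), duration_s = dur),
            class = "uterodyn_analysis")
}

#' Read detection/classification parameters from a YAML config
#'
#' Reads the optional `detection:` and `classification:` blocks used by the
#' command-line interface.
#'
#' @param path YAML file.
#' @return list with `detection` and `classification` sublists (possibly
#'   empty).
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(detection = cfg$detection %||% list(),
       classification = cfg$classification %||% list())
}
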