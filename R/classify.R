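# Rule-based classification of contractions into placental vs uterine.
#
# Gate: only events with a placental volume drop strictly greater than 10 %
# are classified (below that, rater consensus is unreliable and the event is
# "sub-threshold"). Among gated events, a sphericity increase strictly
# greater than 0.005 indicates a placental contraction (bed shortening with
# ballooning of the placenta); otherwise the event is uterine. Mixed
# simultaneous contractions fall into the uterine branch by construction.

RULE_VERSION <- "gate10-sphericity0.005/v1"

#' Classify detected events
#'
#' @param events a `uterodyn_events` data.frame ([event_features()] output).
#' @param volume_gate_pct volume gate, %; strictly-greater comparison.
#' @param sphericity_threshold sphericity-increase threshold;
#'   strictly-greater comparison.
#' @param use_wall_area optionally require a non-placental wall-area change
#'   above `wall_area_threshold_pct` for the placental label (off by
#'   default: no validated threshold exists yet).
#' @param wall_area_threshold_pct threshold for the optional criterion.
#' @return the input with added columns `passes_volume_gate`, `label`
#'   (`"placental"`, `"uterine"` or `"sub-threshold"`) and `rule_version`.
#' @examples
#' ev <- data.frame(max_volume_drop_pct = c(15, 15, 8, 10),
#'                  max_sphericity_change = c(0.010, -0.003, 0.02, 0.02))
#' classify_events(ev)$label
#' @export
classify_events <- function(events, volume_gate_pct = 10,
                            sphericity_threshold = 0.005,
                            use_wall_area = FALSE,
                            wall_area_threshold_pct = NULL) {
  req <- c("max_volume_drop_pct", "max_sphericity_change")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("classify_events: missing feature column(s): ",
         paste(miss, collapse = ", "))
  if (any(is.na(events$max_volume_drop_pct)))
    stop("classify_events: max_volume_drop_pct contains NA")
  gate <- events$max_volume_drop_pct > volume_gate_pct
  placental <- gate & !is.na(events$max_sphericity_change) &
    events$max_sphericity_change > sphericity_threshold
  if (use_wall_area) {
    if (is.null(wall_area_threshold_pct))
      stop("classify_events: use_wall_area requires wall_area_threshold_pct")
    placental <- placental &
      events$max_wall_area_change_pct > wall_area_threshold_pct
  }
  events$passes_volume_gate <- gate
  events$label <- ifelse(!gate, "sub-threshold",
                         ifelse(placental, "placental", "uterine"))
  events$rule_version <- rep(RULE_VERSION, nrow(events))
  events
}

#' Per-session contraction counts and rates
#'
#' @param classified a [classify_events()] result.
#' @param session_duration_s acquisition duration, seconds.
#' @return list with counts and per-hour rates for all events, gated events
#'   (volume drop above the gate), and each label.
#' @export
classify_session <- function(classified, session_duration_s) {
  n_all <- nrow(classified)
  n_gated <- if (n_all) sum(classified$passes_volume_gate) else 0L
  n_pl <- if (n_all) sum(classified$label == "placental") else 0L
  n_ut <- if (n_all) sum(classified$label == "uterine") else 0L
  list(n_all = n_all, n_gated = n_gated,
       n_placental = n_pl, n_uterine = n_ut,
       rate_all_per_h = contraction_rate(n_all, session_duration_s),
       rate_gated_per_h = contraction_rate(n_gated, session_duration_s),
       rate_placental_per_h = contraction_rate(n_pl, session_duration_s),
       rate_uterine_per_h = contraction_rate(n_ut, session_duration_s))
}
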