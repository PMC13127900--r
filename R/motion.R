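# Motion screening by frame-to-frame mask differencing.
#
# Maternal: threshold the R2*-weighted images to a mask of high-signal
# maternal features, remove the uterus (labels 1-3), and sum the voxelwise
# change between consecutive frames. Fetal: same differencing applied to the
# thresholded high-signal amniotic fluid inside the intra-uterine contents
# (label 3). The summed symmetric difference is expressed as % of the
# session-mean mask size so the 2 % high-movement rule is scale-free (the
# normalisation convention is a package choice; see the vignette).

#' Otsu threshold of an intensity sample
#'
#' Maximises the between-class variance over a 256-bin histogram. Used as
#' the default fluid threshold in [fetal_trace()] and available as an
#' alternative for [maternal_trace()].
#'
#' @param x numeric intensities.
#' @param n_bins histogram resolution.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(pmax(ceiling((x - r[1]) / diff(r) * n_bins), 1), n_bins),
                n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) * diff(r) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  bc <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

.mask_diff_trace <- function(masks) {
  n <- length(masks)
  sizes <- vapply(masks, sum, 0)
  msize <- mean(sizes)
  out <- numeric(n)
  if (msize == 0) {
    warning("motion trace: empty mask throughout the session")
    return(out)
  }
  for (i in 2:n)
    out[i] <- 100 * sum(masks[[i]] != masks[[i - 1]]) / msize
  out   # frame 1 movement is defined as 0
}

#' Maternal movement time course
#'
#' @param session a `uterodyn_session`.
#' @param threshold intensity threshold for the high-signal maternal mask;
#'   default the 90th percentile of positive frame-1 intensities, held fixed
#'   across the session.
#' @return numeric per-frame maternal movement, % (first frame 0).
#' @export
maternal_trace <- function(session, threshold = NULL) {
  s1 <- session$signal[[1]]
  if (is.null(threshold))
    threshold <- quantile(s1[s1 > 1e-6], 0.9, names = FALSE)
  masks <- lapply(seq_along(session$signal), function(i)
    session$signal[[i]] > threshold & session$labels[[i]] == 0L)
  structure(.mask_diff_trace(masks), threshold = threshold)
}

#' Fetal movement time course
#'
#' High-signal amniotic fluid is selected within the intra-uterine contents
#' (label 3) with a simple threshold; fetal movement displaces fluid, so the
#' frame-to-frame change of the fluid mask tracks it.
#'
#' @param session a `uterodyn_session`.
#' @param threshold fluid threshold; default an Otsu split of the frame-1
#'   in-mask intensities, which separates the bright fluid from darker fetal
#'   tissue regardless of their volume fractions.
#' @return numeric per-frame fetal movement, % (first frame 0).
#' @export
fetal_trace <- function(session, threshold = NULL) {
  in1 <- session$signal[[1]][session$labels[[1]] == LBL_CONTENT]
  if (!length(in1)) {
    warning("fetal_trace: no intra-uterine content voxels")
    return(numeric(length(session$signal)))
  }
  if (is.null(threshold))
    threshold <- otsu_threshold(in1)
  masks <- lapply(seq_along(session$signal), function(i)
    session$signal[[i]] > threshold & session$labels[[i]] == LBL_CONTENT)
  structure(.mask_diff_trace(masks), threshold = threshold)
}

#' High-movement flag over non-contracting frames
#'
#' A session is a high-movement scan when the mean maternal or fetal
#' movement across all non-contracting time points exceeds
#' `threshold_pct` (2 % by default).
#'
#' @param maternal_pct,fetal_pct per-frame movement traces, %.
#' @param event_intervals data.frame with `start_index`/`end_index`
#'   (e.g. a [detect_events()] result); frames inside any interval are
#'   excluded from the means.
#' @param threshold_pct flag threshold, %.
#' @return list with `high_movement_scan`,
#'   `noncontracting_mean_maternal_pct`, `noncontracting_mean_fetal_pct`.
#' @export
flag_high_movement <- function(maternal_pct, fetal_pct,
                               event_intervals = NULL, threshold_pct = 2) {
  n <- length(maternal_pct)
  keep <- rep(TRUE, n)
  if (!is.null(event_intervals) && nrow(event_intervals))
    for (i in seq_len(nrow(event_intervals)))
      keep[event_intervals$start_index[i]:event_intervals$end_index[i]] <- FALSE
  if (!any(keep)) {
    warning("flag_high_movement: no non-contracting frames; flag undetermined")
    return(list(high_movement_scan = NA,
                noncontracting_mean_maternal_pct = NA_real_,
                noncontracting_mean_fetal_pct = NA_real_))
  }
  mm <- mean(maternal_pct[keep]); fm <- mean(fetal_pct[keep])
  list(high_movement_scan = mm > threshold_pct || fm > threshold_pct,
       noncontracting_mean_maternal_pct = mm,
       noncontracting_mean_fetal_pct = fm)
}

#' Full motion screen of a session
#'
#' @param session a `uterodyn_session`.
#' @param event_intervals optional [detect_events()] result.
#' @param threshold_pct high-movement threshold, %.
#' @return list of class `uterodyn_motion` with `maternal_pct`, `fetal_pct`
#'   and the [flag_high_movement()] summary fields.
#' @export
motion_trace <- function(session, event_intervals = NULL,
                         threshold_pct = 2) {
  m <- maternal_trace(session)
  f <- fetal_trace(session)
  structure(c(list(maternal_pct = as.numeric(m), fetal_pct = as.numeric(f)),
              flag_high_movement(m, f, event_intervals, threshold_pct)),
            class = "uterodyn_motion")
}
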