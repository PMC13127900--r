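# Synthetic dynamic utero-placental MRI sessions with closed-form ground
# truth, emulating a respiratory-triggered multislice R2*-weighted EPI
# acquisition (voxel 2.4 x 2.4 x 6 mm, 10 mm interslice spacing, minimum
# repetition 9 s, mean 15 s, TE 25 ms).

# resting tissue signal model: S = S0 * exp(-TE * R2*), R2* in ms^-1
.TISSUE <- list(
  placenta = c(S0 = 1.00, r2s = 0.035),
  wall     = c(S0 = 0.85, r2s = 0.045),
  fluid    = c(S0 = 1.20, r2s = 0.005),   # amniotic fluid: bright
  fetus    = c(S0 = 0.70, r2s = 0.040),
  mblob    = c(S0 = 1.50, r2s = 0.005),   # high-signal maternal features
  body     = c(S0 = 0.40, r2s = 0.030))

#' Specify one synthetic contraction event
#'
#' @param kind `"placental"`, `"uterine_local"` or `"uterine_uniform"`.
#' @param onset_s,duration_s event window, seconds (`duration_s > 0`).
#' @param amplitude peak fractional placental-volume decrease, in `[0, 0.5]`.
#' @param sphericity_delta peak signed change of placental sphericity imposed
#'   by the shape model. Must be positive for placental events and
#'   non-positive for uterine ones. Defaults: `+0.012` for placental events
#'   (bed shortening with ballooning; comfortably above the 0.005
#'   classification threshold), and `-0.35 * amplitude` for uterine events -
#'   the passive sphericity drop of a slab that thins at near-constant bed
#'   extent, so the uterine morph is thinning-dominant rather than
#'   bed-shortening.
#' @param r2s_delta_per_ms peak placental R2* increase during the event,
#'   ms^-1. Default 0.004 (the scale observed during contractions).
#' @param profile `"raised_cosine"` (default) or `"triangle"` unimodal bump.
#' @return an object of class `uterodyn_event_spec`.
#' @export
event_spec <- function(kind, onset_s, duration_s, amplitude,
                       sphericity_delta = NULL, r2s_delta_per_ms = 0.004,
                       profile = "raised_cosine") {
  kind <- match.arg(kind, c("placental", "uterine_local", "uterine_uniform"))
  if (is.null(sphericity_delta))
    sphericity_delta <- if (kind == "placental") 0.012 else -0.35 * amplitude
  if (!(amplitude >= 0 && amplitude <= 0.5))
    stop("event_spec: amplitude must lie in [0, 0.5]")
  if (duration_s <= 0) stop("event_spec: duration_s must be positive")
  if (kind == "placental" && sphericity_delta <= 0)
    stop("event_spec: placental events require sphericity_delta > 0")
  if (kind != "placental" && sphericity_delta > 0)
    stop("event_spec: uterine events require sphericity_delta <= 0")
  structure(list(kind = kind, onset_s = onset_s, duration_s = duration_s,
                 amplitude = amplitude, sphericity_delta = sphericity_delta,
                 r2s_delta_per_ms = r2s_delta_per_ms, profile = profile),
            class = "uterodyn_event_spec")
}

#' Parametric description of a synthetic phantom session
#'
#' Defaults reproduce the acquisition this package targets (2.4 x 2.4 x 6 mm
#' voxels, 10 mm interslice spacing, TE 25 ms, repetition time minimum 9 s /
#' mean 15 s) on a reduced 96 x 96 x 24 grid, with a third-trimester-scale
#' uterus (cavity ~2 L, placenta ~340 mL).
#'
#' @param grid_shape integer length-3: voxels per axis.
#' @param voxel_size_mm in-plane voxel sizes and slice thickness, mm.
#' @param slice_spacing_mm interslice spacing (>= slice thickness), mm.
#' @param n_frames number of dynamics.
#' @param te_ms echo time, ms.
#' @param tr_min_s,tr_mean_s minimum and mean repetition time, s. Interframe
#'   gaps are drawn as `tr_min_s + Exp(tr_mean_s - tr_min_s)`.
#' @param uterus_semiaxes_mm cavity ellipsoid semi-axes, mm.
#' @param wall_thickness_mm resting uterine wall thickness, mm.
#' @param placenta_cap_angle_deg angular extent of the placental cap, in
#'   (0, 180) degrees.
#' @param placenta_thickness_mm resting placental slab thickness, mm.
#' @param events list of [event_spec()] objects. Events of the same kind must
#'   not overlap in time and must lie within the nominal session duration
#'   `n_frames * tr_mean_s`.
#' @param noise_sd_fraction Gaussian signal noise SD as a fraction of the
#'   resting placental signal.
#' @param motion_events list of `list(frame, type, magnitude_mm)` with type
#'   `"maternal"` (rigid in-plane shift of everything outside the uterus from
#'   that frame on) or `"fetal"` (re-randomised fetal blob pattern inside the
#'   intra-uterine contents from that frame on).
#' @param rng_seed seed for signal noise and blob placement. Label volumes do
#'   not depend on it.
#' @param timing_seed seed for the respiratory-triggered frame times, kept
#'   separate from `rng_seed` so that identical configurations give identical
#'   label volumes regardless of the noise seed.
#' @return an object of class `uterodyn_scenario`.
#' @export
scenario_config <- function(grid_shape = c(96, 96, 24),
                            voxel_size_mm = c(2.4, 2.4, 6),
                            slice_spacing_mm = 10,
                            n_frames = 120,
                            te_ms = 25,
                            tr_min_s = 9, tr_mean_s = 15,
                            uterus_semiaxes_mm = c(80, 70, 85),
                            wall_thickness_mm = 7,
                            placenta_cap_angle_deg = 120,
                            placenta_thickness_mm = 25,
                            events = list(),
                            noise_sd_fraction = 0.02,
                            motion_events = list(),
                            rng_seed = 1L,
                            timing_seed = 74123L) {
  cfg <- structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_size_mm = as.numeric(voxel_size_mm),
         slice_spacing_mm = as.numeric(slice_spacing_mm),
         n_frames = as.integer(n_frames), te_ms = te_ms,
         tr_min_s = tr_min_s, tr_mean_s = tr_mean_s,
         uterus_semiaxes_mm = as.numeric(uterus_semiaxes_mm),
         wall_thickness_mm = wall_thickness_mm,
         placenta_cap_angle_deg = placenta_cap_angle_deg,
         placenta_thickness_mm = placenta_thickness_mm,
         events = events, noise_sd_fraction = noise_sd_fraction,
         motion_events = motion_events,
         rng_seed = as.integer(rng_seed),
         timing_seed = as.integer(timing_seed)),
    class = "uterodyn_scenario")
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  with(cfg, {
    if (any(grid_shape < 4)) stop("scenario: grid_shape too small")
    if (any(voxel_size_mm <= 0) || slice_spacing_mm <= 0 ||
        wall_thickness_mm <= 0 || placenta_thickness_mm <= 0 ||
        any(uterus_semiaxes_mm <= 0))
      stop("scenario: all geometric dimensions must be strictly positive")
    if (!(placenta_cap_angle_deg > 0 && placenta_cap_angle_deg < 180))
      stop("scenario: placenta_cap_angle_deg must lie in (0, 180)")
    if (slice_spacing_mm < voxel_size_mm[3])
      stop("scenario: slice spacing must be at least the slice thickness")
    if (wall_thickness_mm < max(voxel_size_mm[1:2]))
      stop("scenario: grid too coarse to represent the uterine wall (wall ",
           wall_thickness_mm, " mm is thinner than one in-plane voxel)")
    if (n_frames < 1) stop("scenario: n_frames must be >= 1")
    if (tr_min_s <= 0 || tr_mean_s < tr_min_s)
      stop("scenario: need 0 < tr_min_s <= tr_mean_s")
    dur <- n_frames * tr_mean_s
    for (ev in events) {
      if (!inherits(ev, "uterodyn_event_spec"))
        stop("scenario: events must be event_spec() objects")
      if (ev$onset_s < 0 || ev$onset_s + ev$duration_s > dur)
        stop("scenario: event window [", ev$onset_s, ", ",
             ev$onset_s + ev$duration_s,
             "] lies outside the session [0, ", dur, "]")
    }
    if (length(events) > 1) {
      for (kind in unique(vapply(events, `[[`, "", "kind"))) {
        evs <- Filter(function(e) e$kind == kind, events)
        if (length(evs) > 1) {
          on <- vapply(evs, `[[`, 0, "onset_s")
          off <- on + vapply(evs, `[[`, 0, "duration_s")
          o <- order(on)
          if (any(on[o][-1] < off[o][-length(off)]))
            stop("scenario: overlapping events of kind '", kind, "'")
        }
      }
    }
    for (mv in motion_events) {
      if (!is.list(mv) || is.null(mv$frame) || is.null(mv$type))
        stop("scenario: motion_events entries need $frame and $type")
      if (!(mv$type %in% c("maternal", "fetal")))
        stop("scenario: motion event type must be 'maternal' or 'fetal'")
      if (mv$frame < 1 || mv$frame > n_frames)
        stop("scenario: motion event frame out of range")
    }
  })
  invisible(cfg)
}

#' Rasterize a continuous shape model onto the acquisition grid
#'
#' Samples a continuous label function on the multislice grid: in-plane at
#' voxel centres, through-plane with three subsamples across the slice
#' thickness and a per-voxel majority vote, emulating a thick-slice
#' acquisition with an interslice gap.
#'
#' @param label_fun function `(x, y, z) -> integer labels`, taking world
#'   coordinates in mm (origin at the grid centre) and defined everywhere in
#'   the field of view.
#' @param grid_shape integer length-3.
#' @param geom a [grid_geometry()].
#' @param subsamples odd number of through-plane subsamples (>= 3).
#' @return integer 3D array of labels.
#' @export
rasterize_to_slices <- function(label_fun, grid_shape, geom, subsamples = 3) {
  stopifnot(subsamples >= 3, subsamples %% 2 == 1)
  co <- .grid_coords(grid_shape, geom)
  offs <- seq(-geom$voxel_size_mm[3] / 2, geom$voxel_size_mm[3] / 2,
              length.out = subsamples + 2)[-c(1, subsamples + 2)]
  labs <- lapply(offs, function(o)
    as.integer(label_fun(co$x, co$y, co$z + o)))
  out <- .majority_label(labs)
  array(out, grid_shape)
}

# voxel-centre world coordinates (vectors of length prod(grid_shape)),
# origin at the grid centre
.grid_coords <- function(grid_shape, geom) {
  vs <- geom$voxel_size_mm
  xs <- (seq_len(grid_shape[1]) - (grid_shape[1] + 1) / 2) * vs[1]
  ys <- (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * vs[2]
  zs <- (seq_len(grid_shape[3]) - (grid_shape[3] + 1) / 2) *
    geom$slice_spacing_mm
  list(x = rep(xs, times = grid_shape[2] * grid_shape[3]),
       y = rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]),
       z = rep(zs, each = grid_shape[1] * grid_shape[2]))
}

# majority vote over an odd number of integer label vectors
.majority_label <- function(labs) {
  if (length(labs) == 3) {
    l1 <- labs[[1]]; l2 <- labs[[2]]; l3 <- labs[[3]]
    return(ifelse(l1 == l3, l1, l2))
  }
  m <- do.call(cbind, labs)
  apply(m, 1, function(r) {
    tb <- tabulate(r + 1L)
    which.max(tb) - 1L
  })
}

#' Simulate a dynamic utero-placental MRI session
#'
#' Generates a full synthetic session: per-frame label volumes (thick-slice
#' majority-vote rasterisation of the continuous morphing model), matching
#' R2*-weighted signal volumes with Gaussian noise, irregular
#' respiratory-triggered timestamps, and a ground-truth event table with
#' analytic onset/offset, half-maximum duration and peak fractional volume
#' change for every injected contraction.
#'
#' Incompressibility: the cavity radius is adjusted so the intra-uterine
#' content volume (label 3) is conserved exactly in the continuous model;
#' rasterised content volume is conserved within rasterisation error.
#'
#' @param config a [scenario_config()].
#' @return an object of class `uterodyn_session`: a list with `timestamps_s`,
#'   `labels` (list of integer 3D arrays), `signal` (list of numeric 3D
#'   arrays), `geometry`, `te_ms`, `config`, `state` (per-frame continuous
#'   model solution) and `ground_truth` (data.frame with columns `event_id`,
#'   `kind`, `onset_s`, `offset_s`, `halfmax_duration_s`,
#'   `peak_volume_drop_frac`, `fully_observed`).
#' @export
simulate_session <- function(config) {
  validate_scenario(config)
  geom <- grid_geometry(config$voxel_size_mm, config$slice_spacing_mm)
  n <- config$n_frames

  ts <- with_seed(config$timing_seed, {
    gaps <- config$tr_min_s +
      rexp(max(n - 1, 0), rate = 1 / max(config$tr_mean_s - config$tr_min_s,
                                         1e-9))
    cumsum(c(0, gaps))
  })

  state <- phantom_state(config, ts)
  co <- .grid_coords(config$grid_shape, geom)
  offs <- c(-config$voxel_size_mm[3] / 4, 0, config$voxel_size_mm[3] / 4)

  # frame-independent geometry in u-space, per z-subsample
  ax <- config$uterus_semiaxes_mm
  geo_sub <- lapply(offs, function(o) {
    u1 <- co$x / ax[1]; u2 <- co$y / ax[2]; u3 <- (co$z + o) / ax[3]
    rho <- sqrt(u1^2 + u2^2 + u3^2)
    theta <- acos(pmin(pmax(ifelse(rho > 0, u3 / rho, 1), -1), 1))
    list(rho = rho, theta = theta)
  })
  r_geo <- prod(ax)^(1 / 3)
  tau_w <- config$wall_thickness_mm / r_geo

  labels_from_state <- function(g, srow) {
    thick <- if (srow$wall_local > 0) {
      tau_w * (srow$wall_thick +
                 srow$wall_local * exp(-((g$theta - 150 * pi / 180) /
                                           (25 * pi / 180))^2))
    } else tau_w * srow$wall_thick
    lab <- integer(length(g$rho))
    lab[g$rho >= srow$rc & g$rho < srow$rc + thick] <- LBL_WALL
    inside <- g$rho < srow$rc
    lab[inside] <- LBL_CONTENT
    lab[inside & g$rho >= srow$ri & g$theta <= srow$beta] <- LBL_PLACENTA
    lab
  }

  # body and blob geometry (signal only; labels never depend on rng_seed)
  out_semi <- ax * (1 + tau_w)
  fov_half <- config$grid_shape * c(config$voxel_size_mm[1:2],
                                    config$slice_spacing_mm) / 2
  body_semi <- pmin(1.35 * out_semi, fov_half - 2)
  mot <- config$motion_events
  mat_frames <- sort(vapply(Filter(function(m) m$type == "maternal", mot),
                            `[[`, 0, "frame"))
  fet_frames <- sort(vapply(Filter(function(m) m$type == "fetal", mot),
                            `[[`, 0, "frame"))
  mat_mags <- vapply(Filter(function(m) m$type == "maternal", mot),
                     function(m) m$magnitude %||% 10, 0)

  sim <- with_seed(config$rng_seed, {
    nb <- 5
    phis <- runif(nb, 0, 2 * pi)
    mblob <- cbind((out_semi[1] + 22) * cos(phis),
                   (out_semi[2] + 22) * sin(phis),
                   runif(nb, -0.4, 0.4) * out_semi[3])
    mblob_r <- runif(nb, 10, 16)
    fetal_pattern <- function() {
      nf <- 6
      dir <- matrix(rnorm(nf * 3), nf)
      dir <- dir / sqrt(rowSums(dir^2))
      rho <- runif(nf, 0.1, 0.7)
      list(centers = dir * rho %o% c(1, 1, 1) * rep(ax, each = nf),
           radius = runif(nf, 12, 20))
    }
    fpatterns <- replicate(length(fet_frames) + 1, fetal_pattern(),
                           simplify = FALSE)
    s_rest <- .TISSUE$placenta["S0"] *
      exp(-config$te_ms * .TISSUE$placenta["r2s"])
    noise_sd <- config$noise_sd_fraction * as.numeric(s_rest)

    labels <- vector("list", n)
    signal <- vector("list", n)
    blob_mask <- function(centers, radius, xs, ys, zs) {
      m <- logical(length(xs))
      for (b in seq_len(nrow(centers)))
        m <- m | ((xs - centers[b, 1])^2 + (ys - centers[b, 2])^2 +
                    (zs - centers[b, 3])^2) < radius[b]^2
      m
    }
    tis <- .TISSUE
    te <- config$te_ms
    sval <- function(p, add = 0) as.numeric(p["S0"] * exp(-te * (p["r2s"] + add)))
    # blob/body masks change only at motion events: cache per epoch
    cur_shift <- NA_real_; cur_fp <- -1L
    body <- NULL; mblob_m <- NULL; fet_m <- NULL
    for (i in seq_len(n)) {
      srow <- state[i, ]
      labs <- .majority_label(lapply(geo_sub, labels_from_state, srow = srow))
      labels[[i]] <- array(labs, config$grid_shape)
      # cumulative maternal shift and current fetal pattern at this frame
      shift <- sum(mat_mags[mat_frames <= i])
      ifp <- sum(fet_frames <= i) + 1L
      if (!identical(shift, cur_shift)) {
        xs <- co$x - shift
        body <- (xs / body_semi[1])^2 + (co$y / body_semi[2])^2 +
          (co$z / body_semi[3])^2 < 1
        mblob_m <- blob_mask(mblob, mblob_r, xs, co$y, co$z)
        cur_shift <- shift
      }
      if (ifp != cur_fp) {
        fp <- fpatterns[[ifp]]
        fet_m <- blob_mask(fp$centers, fp$radius, co$x, co$y, co$z)
        cur_fp <- ifp
      }
      S <- numeric(length(labs))
      outside <- labs == 0L
      S[outside & body] <- sval(tis$body)
      S[labs == LBL_WALL] <- sval(tis$wall)
      S[labs == LBL_PLACENTA] <- sval(tis$placenta, srow$r2s_add)
      inc <- labs == LBL_CONTENT
      if (any(inc)) {
        S[inc] <- sval(tis$fluid)
        S[inc & fet_m] <- sval(tis$fetus)
      }
      S[outside & mblob_m] <- sval(tis$mblob)
      if (noise_sd > 0) S <- S + rnorm(length(S), 0, noise_sd)
      signal[[i]] <- array(S, config$grid_shape)
    }
    list(labels = labels, signal = signal)
  })

  evs <- config$events
  gt <- if (length(evs)) {
    data.frame(
      event_id = seq_along(evs),
      kind = vapply(evs, `[[`, "", "kind"),
      onset_s = vapply(evs, `[[`, 0, "onset_s"),
      offset_s = vapply(evs, function(e) e$onset_s + e$duration_s, 0),
      halfmax_duration_s = vapply(evs, function(e)
        .profile_halfmax_s(e$profile, e$duration_s), 0),
      peak_volume_drop_frac = vapply(evs, `[[`, 0, "amplitude"))
  } else {
    data.frame(event_id = integer(0), kind = character(0),
               onset_s = numeric(0), offset_s = numeric(0),
               halfmax_duration_s = numeric(0),
               peak_volume_drop_frac = numeric(0))
  }
  gt$fully_observed <- gt$onset_s >= ts[1] & gt$offset_s <= ts[n]

  structure(list(timestamps_s = ts, labels = sim$labels,
                 signal = sim$signal, geometry = geom, te_ms = config$te_ms,
                 config = config, state = state, ground_truth = gt,
                 provenance = "uterodyn phantom"),
            class = "uterodyn_session")
}

# analytic half-maximum width of the volume deviation for a unit bump
.profile_halfmax_s <- function(profile, duration_s) {
  if (identical(profile, "raised_cosine")) duration_s / 2
  else if (identical(profile, "triangle")) duration_s / 2
  else stop("unknown profile")
}

#' @export
print.uterodyn_session <- function(x, ...) {
  cat("uterodyn_session:", length(x$timestamps_s), "frames over",
      round(max(x$timestamps_s) / 60, 1), "min; grid",
      paste(x$config$grid_shape, collapse = "x"), "\n")
  cat("  events:", nrow(x$ground_truth), " motion:",
      length(x$config$motion_events), "\n")
  invisible(x)
}

#' Write / read a session to disk
#'
#' Writes one 4D NIfTI each for labels and signal, a JSON sidecar with
#' timestamps and acquisition parameters, and the ground-truth event table
#' as CSV (when present).
#'
#' @param session a `uterodyn_session`.
#' @param dir output directory (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a `uterodyn_session` (without the continuous-model `state`).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- dim(session$labels[[1]])
  n <- length(session$labels)
  lab4 <- array(0L, c(gs, n)); sig4 <- array(0, c(gs, n))
  for (i in seq_len(n)) {
    lab4[, , , i] <- session$labels[[i]]
    sig4[, , , i] <- session$signal[[i]]
  }
  vs <- c(session$geometry$voxel_size_mm[1:2],
          session$geometry$slice_spacing_mm)
  write_nifti(lab4, file.path(dir, "labels.nii"), vs, datatype = "uint8")
  write_nifti(sig4, file.path(dir, "signal.nii"), vs, datatype = "float32")
  jsonlite::write_json(
    list(timestamps_s = session$timestamps_s, te_ms = session$te_ms,
         voxel_size_mm = session$geometry$voxel_size_mm,
         slice_spacing_mm = session$geometry$slice_spacing_mm,
         provenance = session$provenance %||% "external"),
    file.path(dir, "acquisition.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(session$ground_truth) && nrow(session$ground_truth))
    write.csv(session$ground_truth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "acquisition.json"),
                              simplifyVector = TRUE)
  lab <- read_nifti(file.path(dir, "labels.nii"))$data
  sig <- read_nifti(file.path(dir, "signal.nii"))$data
  n <- dim(lab)[4]
  gt_path <- file.path(dir, "ground_truth.csv")
  structure(list(
    timestamps_s = as.numeric(meta$timestamps_s),
    labels = lapply(seq_len(n), function(i) lab[, , , i, drop = TRUE]),
    signal = lapply(seq_len(n), function(i) sig[, , , i, drop = TRUE]),
    geometry = grid_geometry(as.numeric(meta$voxel_size_mm),
                             as.numeric(meta$slice_spacing_mm)),
    te_ms = meta$te_ms, config = NULL, state = NULL,
    ground_truth = if (file.exists(gt_path)) read.csv(gt_path) else NULL,
    provenance = meta$provenance), class = "uterodyn_session")
}
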