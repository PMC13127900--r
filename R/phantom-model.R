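# Continuous utero-placental shape model.
#
# The uterine cavity is an ellipsoid (semi-axes a, b, c). All morphology is
# defined in "u-space", the coordinates u = (x/a, y/b, z/c) in which the
# cavity is the unit ball; world volumes are u-space volumes times abc.
# The placenta is a spherical-cap slab attached to the cavity surface around
# the +z pole: { rho_i <= rho < rho_c, theta <= beta } with rho = |u|,
# theta the polar angle from +z. The non-placental uterine wall is the shell
# rho_c <= rho < rho_out(theta).
#
# Contractions morph (rho_c, rho_i, beta) analytically:
#   * the placental volume is driven directly by the event amplitude,
#   * the cavity radius rho_c follows from conservation of the intra-uterine
#     contents (fetus + fluid are incompressible),
#   * beta (bed extent) and the slab thickness are solved so that the slab
#     attains a prescribed sphericity change: placental contractions shorten
#     the bed and balloon the slab (sphericity up), uterine contractions
#     mostly thin it (sphericity down).
# Because every frame state is the solution of closed-form equations, volume,
# area and sphericity ground truth are available without rasterisation.

# volume of the spherical-cap slab, u-space
cap_slab_volume <- function(rc, ri, beta) {
  (2 * pi / 3) * (rc^3 - ri^3) * (1 - cos(beta))
}

# closed-surface area of the cap slab: outer cap + inner cap + conical band
cap_slab_area <- function(rc, ri, beta) {
  2 * pi * (1 - cos(beta)) * (rc^2 + ri^2) + pi * sin(beta) * (rc^2 - ri^2)
}

cap_slab_sphericity <- function(rc, ri, beta) {
  sphericity(cap_slab_volume(rc, ri, beta), cap_slab_area(rc, ri, beta))
}

# area of the cavity surface covered by the placental bed, u-space
cap_bed_area <- function(rc, beta) 2 * pi * rc^2 * (1 - cos(beta))

# inner surface of the wall not covered by placenta, u-space
cap_free_wall_area <- function(rc, beta) 2 * pi * rc^2 * (1 + cos(beta))

# Solve (beta, ri) so that the slab on a cavity of radius rc attains the
# target u-space volume and sphericity. Monotonicity: at fixed volume,
# sphericity decreases as beta grows (thin wide slab) and increases as beta
# shrinks (thick blocky slab), so a 1D root in beta suffices.
solve_cap_state <- function(rc, v_target, psi_target, beta_hint = NULL) {
  stopifnot(rc > 0, v_target > 0)
  ri_of_beta <- function(beta) {
    ri3 <- rc^3 - 3 * v_target / (2 * pi * (1 - cos(beta)))
    if (ri3 < 0) return(NA_real_)
    ri3^(1 / 3)
  }
  psi_of_beta <- function(beta) {
    ri <- ri_of_beta(beta)
    if (is.na(ri) || ri >= rc) return(NA_real_)
    cap_slab_sphericity(rc, ri, beta)
  }
  # feasible beta: slab must fit inside the cavity (ri >= 0)
  cmin <- 1 - 3 * v_target / (2 * pi * rc^3)
  beta_lo <- if (cmin >= 1) 1e-4 else acos(max(min(cmin, 1), -1)) + 1e-6
  beta_hi <- pi / 2 * 0.999
  if (beta_lo >= beta_hi)
    stop("solve_cap_state: target volume too large for the cavity")
  grid <- seq(beta_lo + 1e-6, beta_hi, length.out = 64)
  psis <- vapply(grid, psi_of_beta, numeric(1))
  ok <- which(is.finite(psis))
  if (!length(ok)) stop("solve_cap_state: no feasible slab geometry")
  grid <- grid[ok]; psis <- psis[ok]
  if (psi_target >= max(psis)) {
    beta <- grid[which.max(psis)]
  } else if (psi_target <= min(psis)) {
    beta <- grid[which.min(psis)]
  } else {
    i <- which(diff(sign(psis - psi_target)) != 0)[1]
    beta <- uniroot(function(b) psi_of_beta(b) - psi_target,
                    lower = grid[i], upper = grid[i + 1],
                    tol = 1e-10)$root
  }
  ri <- ri_of_beta(beta)
  list(beta = beta, ri = ri, rc = rc,
       psi = cap_slab_sphericity(rc, ri, beta),
       v = cap_slab_volume(rc, ri, beta))
}

# raised-cosine unimodal bump on [onset, onset + duration]
event_profile <- function(t, onset_s, duration_s, profile = "raised_cosine") {
  x <- (t - onset_s) / duration_s
  inside <- x > 0 & x < 1
  out <- numeric(length(t))
  if (identical(profile, "raised_cosine")) {
    out[inside] <- 0.5 * (1 - cos(2 * pi * x[inside]))
  } else if (identical(profile, "triangle")) {
    out[inside] <- 1 - abs(2 * x[inside] - 1)
  } else stop("unknown event profile: ", profile)
  out
}

# Full continuous state of the phantom at times t (vectorised): returns a
# data.frame with one row per time point holding the solved morphology and
# the analytic placental measurements in world units.
phantom_state <- function(config, t) {
  ax <- config$uterus_semiaxes_mm
  abc <- prod(ax)
  r_geo <- abc^(1 / 3)
  beta0 <- config$placenta_cap_angle_deg / 2 * pi / 180
  tau0 <- config$placenta_thickness_mm / r_geo
  if (tau0 >= 1) stop("phantom_state: placenta thicker than the cavity")
  v_p0 <- cap_slab_volume(1, 1 - tau0, beta0)
  psi0 <- cap_slab_sphericity(1, 1 - tau0, beta0)
  v_c0 <- 4 * pi / 3 - v_p0
  tau_w <- config$wall_thickness_mm / r_geo

  drop <- numeric(length(t)); dpsi <- numeric(length(t))
  r2s <- numeric(length(t))
  wall_thick <- rep(1, length(t))     # uniform wall thickening factor
  wall_local <- numeric(length(t))    # local bump amplitude
  for (ev in config$events) {
    f <- event_profile(t, ev$onset_s, ev$duration_s, ev$profile)
    drop <- drop + ev$amplitude * f
    dpsi <- dpsi + ev$sphericity_delta * f
    r2s <- r2s + ev$r2s_delta_per_ms * f
    if (ev$kind == "uterine_uniform") wall_thick <- wall_thick + 0.5 * f
    if (ev$kind == "uterine_local")   wall_local <- wall_local + 1.5 * f
  }
  drop <- pmin(drop, 0.95)

  n <- length(t)
  out <- data.frame(t = t, rc = NA_real_, ri = NA_real_, beta = NA_real_,
                    wall_thick = wall_thick, wall_local = wall_local,
                    r2s_add = r2s,
                    v_placenta_mm3 = NA_real_, a_placenta_mm2 = NA_real_,
                    psi = NA_real_, bed_area_mm2 = NA_real_,
                    free_wall_area_mm2 = NA_real_)
  for (i in seq_len(n)) {
    v_t <- v_p0 * (1 - drop[i])
    psi_t <- psi0 + dpsi[i]
    rc <- ((v_c0 + v_t) * 3 / (4 * pi))^(1 / 3)
    st <- solve_cap_state(rc, v_t, psi_t)
    out$rc[i] <- st$rc; out$ri[i] <- st$ri; out$beta[i] <- st$beta
    out$v_placenta_mm3[i] <- st$v * abc
    # world area/sphericity are exact for a spherical cavity and a controlled
    # approximation for mildly anisotropic ones (documented in the vignette)
    out$a_placenta_mm2[i] <- cap_slab_area(st$rc, st$ri, st$beta) * r_geo^2
    out$psi[i] <- st$psi
    out$bed_area_mm2[i] <- cap_bed_area(st$rc, st$beta) * r_geo^2
    out$free_wall_area_mm2[i] <- cap_free_wall_area(st$rc, st$beta) * r_geo^2
  }
  attr(out, "rest") <- list(v_p0 = v_p0 * abc, psi0 = psi0,
                            v_c0 = v_c0 * abc, tau_w = tau_w,
                            r_geo = r_geo, beta0 = beta0)
  out
}

# Label evaluator for one frame state at world points. Returns integer labels.
# wall_local thickening is a Gaussian bump in polar angle centred away from
# the placental cap.
phantom_labels_at <- function(config, state_row, x, y, z) {
  ax <- config$uterus_semiaxes_mm
  r_geo <- prod(ax)^(1 / 3)
  tau_w <- config$wall_thickness_mm / r_geo
  u1 <- x / ax[1]; u2 <- y / ax[2]; u3 <- z / ax[3]
  rho <- sqrt(u1^2 + u2^2 + u3^2)
  ctheta <- ifelse(rho > 0, u3 / rho, 1)
  theta <- acos(pmin(pmax(ctheta, -1), 1))
  thick <- tau_w * (state_row$wall_thick +
                      state_row$wall_local *
                        exp(-((theta - 150 * pi / 180) / (25 * pi / 180))^2))
  rho_out <- state_row$rc + thick
  lab <- integer(length(rho))
  inside_cavity <- rho < state_row$rc
  lab[rho >= state_row$rc & rho < rho_out] <- LBL_WALL
  placenta <- inside_cavity & rho >= state_row$ri & theta <= state_row$beta
  lab[inside_cavity] <- LBL_CONTENT
  lab[placenta] <- LBL_PLACENTA
  lab
}
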