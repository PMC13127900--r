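# Group statistics: Mann-Whitney U with an exact small-sample route, and
# cohort-style median (LQ, UQ) summaries.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample sizes up to
#' `exact_threshold` the null distribution of U is enumerated exactly over
#' all assignments of the pooled (midranked) values, and the p-value is
#' \eqn{P(|U - n_x n_y/2| \ge |u - n_x n_y/2|)}. For larger samples the
#' normal approximation with tie correction and continuity correction is
#' used. Midranks handle ties in both routes, so
#' `U(x, y) + U(y, x) = n_x n_y` always.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default: exact when `length(x) + length(y) <= exact_threshold`.
#' @param exact_threshold combined-size switch, default 16.
#' @return list with `U` (statistic for `x`), `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_threshold = 16) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("mann_whitney_u: both groups must be non-empty")
  pooled <- c(x, y)
  rk <- rank(pooled)   # midranks
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (is.null(exact)) exact <- (nx + ny) <= exact_threshold
  if (exact) {
    combs <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(rk[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) { p <- 1; }
    else {
      z <- (u - mu)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation (tie + continuity corrected)"
  }
  list(U = u, p_value = p, method = method)
}

#' Compare placental vs uterine contraction features
#'
#' Two-sided Mann-Whitney U per feature with medians and IQRs per group,
#' plus the Bonferroni-adjusted significance threshold
#' `alpha_base / n_comparisons` (0.01 / 5 = 0.002 for the default feature
#' set).
#'
#' @param classified a [classify_events()] result (possibly pooled over
#'   sessions); only rows labelled `"placental"` or `"uterine"` enter.
#' @param features feature columns to compare.
#' @param alpha_base base significance threshold, default 0.01.
#' @return data.frame of class `uterodyn_comparisons`: one row per feature
#'   with `n_placental`, `n_uterine`, per-group `median`/`lq`/`uq`, `U`,
#'   `p_value`, `alpha_base`, `alpha_bonferroni`, `significant`. Features
#'   with an empty group are skipped with a message.
#' @export
compare_groups <- function(classified,
                           features = c("halfmax_duration_min",
                                        "max_volume_drop_pct",
                                        "dr2s_change_per_ms",
                                        "max_wall_area_change_pct",
                                        "max_sphericity_change"),
                           alpha_base = 0.01) {
  alpha_bonf <- alpha_base / length(features)
  rows <- list()
  for (f in features) {
    if (!f %in% names(classified)) {
      message("compare_groups: feature '", f, "' absent; skipped")
      next
    }
    xp <- classified[[f]][classified$label == "placental"]
    xu <- classified[[f]][classified$label == "uterine"]
    xp <- xp[!is.na(xp)]; xu <- xu[!is.na(xu)]
    if (!length(xp) || !length(xu)) {
      message("compare_groups: empty group for '", f, "'; skipped")
      next
    }
    mw <- mann_whitney_u(xp, xu)
    qp <- quantile(xp, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    qu <- quantile(xu, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    rows[[f]] <- data.frame(
      feature = f, n_placental = length(xp), n_uterine = length(xu),
      median_placental = qp[2], lq_placental = qp[1], uq_placental = qp[3],
      median_uterine = qu[2], lq_uterine = qu[1], uq_uterine = qu[3],
      U = mw$U, p_value = mw$p_value,
      alpha_base = alpha_base, alpha_bonferroni = alpha_bonf,
      significant = mw$p_value < alpha_bonf)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("uterodyn_comparisons", "data.frame")
  out
}

.med_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], lq = q[1], uq = q[3])
}

#' Cohort summary across sessions
#'
#' Median (lower quartile, upper quartile) of per-session contraction rates
#' and of per-event features, for all events and for the subset above the
#' volume gate, mirroring the reporting convention
#' "median (LQ, UQ)". Quartiles use linear interpolation between order
#' statistics (R type 7), pinned here as the package convention.
#'
#' @param session_results list with one entry per session, each a list with
#'   `events` (a [classify_events()] result) and `duration_s`.
#' @param features per-event feature columns to summarise.
#' @param volume_gate_pct gate used for the `gated` block.
#' @return list of class `uterodyn_cohort` with `n_sessions`, `rates`
#'   (all/gated: median, lq, uq of per-session rates per hour) and
#'   `features` (a data.frame with per-feature median/lq/uq over all and
#'   gated events; empty subsets give an `NA` row with a notice).
#' @export
summarize_cohort <- function(session_results,
                             features = c("halfmax_duration_min",
                                          "max_volume_drop_pct",
                                          "dr2s_change_per_ms",
                                          "max_wall_area_change_pct",
                                          "max_sphericity_change"),
                             volume_gate_pct = 10) {
  stopifnot(length(session_results) >= 1)
  rates_all <- vapply(session_results, function(s)
    contraction_rate(nrow(s$events), s$duration_s), 0)
  rates_gated <- vapply(session_results, function(s)
    contraction_rate(sum(s$events$max_volume_drop_pct > volume_gate_pct),
                     s$duration_s), 0)
  ev <- do.call(rbind, lapply(session_results, `[[`, "events"))
  gated <- ev[ev$max_volume_drop_pct > volume_gate_pct, , drop = FALSE]
  feat_row <- function(d, f) {
    x <- d[[f]]
    x <- x[!is.na(x)]
    if (!length(x)) {
      message("summarize_cohort: no events for '", f, "' in subset")
      return(c(median = NA_real_, lq = NA_real_, uq = NA_real_))
    }
    .med_iqr(x)
  }
  feats <- do.call(rbind, lapply(features, function(f)
    data.frame(feature = f, t(feat_row(ev, f)),
               t(`names<-`(feat_row(gated, f),
                           c("median_gated", "lq_gated", "uq_gated"))))))
  structure(list(n_sessions = length(session_results),
                 rates = list(all = .med_iqr(rates_all),
                              gated = .med_iqr(rates_gated)),
                 features = feats),
            class = "uterodyn_cohort")
}
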