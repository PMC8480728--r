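#' Downstream preferred-phase trajectory
#'
#' `psi_l4i(t) = psi(t) + nu * d`, wrapped; samples where the profile's first
#' Fourier component is below tolerance carry no preferred phase and are
#' flagged invalid.
#'
#' @param traj an `stdp_trajectory`.
#' @param tol `w_tilde` threshold below which the phase is undefined.
#' @return tibble with `time`, `psi_l4i`, `valid`.
#' @export
phase_trajectory <- function(traj, tol = 1e-12) {
  stopifnot(inherits(traj, "stdp_trajectory"))
  op <- traj$order_params
  valid <- op$w_tilde > tol & !is.na(op$psi)
  if (!any(valid)) abort("no valid preferred phase anywhere along the trajectory.")
  tibble(time = op$time,
         psi_l4i = wrap_angle(op$psi + traj$model$nu * traj$model$delay),
         valid = valid)
}

#' Unwrapped drift velocity of a phase series
#'
#' Unwraps the 2*pi jumps and differentiates by central differences;
#' an optional moving average smooths the velocity. The series must be
#' sampled densely relative to the drift (largest wrapped step below pi/4),
#' otherwise unwrapping is ambiguous and an error asks for a finer record
#' cadence.
#'
#' @param phases wrapped phase series, radians.
#' @param times sample times (strictly increasing).
#' @param smoothing_window moving-average width in samples (0 = none).
#' @return tibble with `time`, `phase_unwrapped`, `velocity` (rad per unit
#'   time; endpoints use one-sided differences).
#' @export
unwrap_and_velocity <- function(phases, times, smoothing_window = 0) {
  stopifnot(length(phases) == length(times), length(phases) >= 3)
  steps <- abs(circ_diff(phases[-1], phases[-length(phases)]))
  if (max(steps) > pi / 4) {
    abort(paste0(
      "phase series undersampled (max wrapped step ",
      sprintf("%.2f", max(steps)),
      " rad > pi/4); record the trajectory at a finer cadence."),
      class = "whiskstdp_undersampled")
  }
  u <- unwrap_angle(phases)
  n <- length(u)
  v <- numeric(n)
  v[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)])
  v[1] <- (u[2] - u[1]) / (times[2] - times[1])
  v[n] <- (u[n] - u[n - 1]) / (times[n] - times[n - 1])
  if (smoothing_window > 1) {
    k <- rep(1 / smoothing_window, smoothing_window)
    sm <- stats::filter(v, k, sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  tibble(time = times, phase_unwrapped = u, velocity = v)
}

#' Temporal distribution of the downstream preferred phase
#'
#' The stationary distribution induced by the drifting limit cycle: the
#' post-transient phase series is truncated to a whole number of 2*pi drift
#' cycles (partial cycles bias the histogram), histogrammed with
#' time-step weights, and fitted with a von Mises distribution
#' ([fit_von_mises()]). At least 3 full cycles are required. The single
#' von Mises fit is knowingly misspecified for bimodal regimes; a flag is
#' raised when the fitted density misses the histogram by more than 0.2 in
#' sup-norm.
#'
#' @param traj an `stdp_trajectory`.
#' @param transient_fraction initial fraction of the run discarded before
#'   cycle counting (default 0.5; limit-cycle statistics are
#'   initialization-independent).
#' @param n_bins histogram bins (default 36, i.e. 10 degrees).
#' @param fit_method `"ml"` (default) or `"nls"` passed to
#'   [fit_von_mises()].
#' @param min_cycles minimum whole drift cycles required (default 3).
#' @return object of class `phase_distribution`: histogram tibble
#'   (`mid`, `density`), `fit` (a `vm_spec`), `n_cycles`, `n_samples`,
#'   `misspecified` flag.
#' @export
temporal_phase_distribution <- function(traj, transient_fraction = 0.5,
                                        n_bins = 36, fit_method = "ml",
                                        min_cycles = 3) {
  pt <- phase_trajectory(traj)
  keep <- pt$valid
  pt <- pt[keep, ]
  start <- floor(nrow(pt) * transient_fraction) + 1
  pt <- pt[start:nrow(pt), ]
  u <- tryCatch(
    unwrap_and_velocity(pt$psi_l4i, pt$time)$phase_unwrapped,
    whiskstdp_undersampled = function(e) rlang::cnd_signal(e))
  total <- u[length(u)] - u[1]
  n_cycles <- floor(abs(total) / (2 * pi))
  if (n_cycles < min_cycles) {
    abort(sprintf(
      "only %d whole drift cycles after the transient (need >= %d); run longer.",
      n_cycles, min_cycles), class = "whiskstdp_too_few_cycles")
  }
  # whole cycles, ending at the last sample
  target <- u[length(u)] - sign(total) * 2 * pi * n_cycles
  first <- if (total > 0) which(u >= target)[1] else which(u <= target)[1]
  idx <- first:length(u)
  theta <- pt$psi_l4i[idx]
  tw <- local({  # per-sample time weight = half-neighbourhood width
    tt <- pt$time[idx]
    d <- diff(tt)
    c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  })
  hist <- weighted_phase_histogram(theta, tw, n_bins)
  fit <- fit_von_mises(theta, weights = tw, method = fit_method,
                       n_bins = n_bins)
  sup <- max(abs(von_mises_density(fit, hist$mid) - hist$density))
  structure(
    list(histogram = hist, fit = fit,
         n_cycles = n_cycles, n_samples = length(theta),
         n_bins = n_bins, fit_method = fit_method,
         misspecified = sup > 0.2, sup_distance = sup),
    class = "phase_distribution")
}

#' @export
print.phase_distribution <- function(x, ...) {
  cat(sprintf(
    "<phase distribution> %d whole drift cycles, %d samples, %d bins\n",
    x$n_cycles, x$n_samples, x$n_bins))
  cat(sprintf("  von Mises fit (%s): kappa = %.3f, psi = %.3f rad%s\n",
              x$fit_method, x$fit$kappa, x$fit$psi,
              if (x$misspecified) "  [poor fit: likely not unimodal]" else ""))
  invisible(x)
}

#' Occupancy versus inverse drift speed
#'
#' On a periodic orbit the time spent near a phase is proportional to the
#' inverse drift speed there; this pairs the time-weighted occupancy
#' histogram with the normalized inverse speed, binned the same way, for
#' the conservation-of-time check.
#'
#' @inheritParams temporal_phase_distribution
#' @return tibble with `mid`, `density`, `inv_speed_density`.
#' @export
occupancy_vs_velocity <- function(traj, transient_fraction = 0.5, n_bins = 36) {
  pt <- phase_trajectory(traj)
  pt <- pt[pt$valid, ]
  start <- floor(nrow(pt) * transient_fraction) + 1
  pt <- pt[start:nrow(pt), ]
  uv <- unwrap_and_velocity(pt$psi_l4i, pt$time)
  dist <- temporal_phase_distribution(traj, transient_fraction, n_bins)
  # mean inverse speed per occupancy bin, normalized to a density
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- pmin(findInterval(wrap_angle(pt$psi_l4i), edges,
                           rightmost.closed = TRUE), n_bins)
  inv <- 1 / pmax(abs(uv$velocity), 1e-12)
  m <- vapply(seq_len(n_bins),
              function(b) if (any(bin == b)) mean(inv[bin == b]) else 0,
              numeric(1))
  width <- 2 * pi / n_bins
  tibble(mid = dist$histogram$mid,
         density = dist$histogram$density,
         inv_speed_density = m / (sum(m) * width))
}

#' Downstream modulation-depth series
#'
#' `gamma_l4i(t) = gamma * w_tilde(t) / w_bar(t)`; the reported summary is
#' the time average over the post-transient segment.
#'
#' @param traj an `stdp_trajectory`.
#' @param transient_fraction fraction discarded for the summary average.
#' @return tibble with `time`, `gamma_l4i`; attribute `mean` holds the
#'   post-transient time average.
#' @export
modulation_series <- function(traj, transient_fraction = 0.5) {
  stopifnot(inherits(traj, "stdp_trajectory"))
  op <- traj$order_params
  if (any(op$w_bar <= 0)) abort("w_bar must stay positive along the trajectory.")
  g <- traj$model$gamma * op$w_tilde / op$w_bar
  out <- tibble(time = op$time, gamma_l4i = g)
  start <- floor(nrow(out) * transient_fraction) + 1
  attr(out, "mean") <- mean(g[start:length(g)])
  out
}

#' Summarize a run as JSON
#'
#' Writes `{kappa_l4i, psi_l4i_rad, gamma_l4i_mean, n_cycles, flags}` plus a
#' histogram CSV when paths are given.
#'
#' @param dist a `phase_distribution`.
#' @param traj the trajectory it came from.
#' @param json_path,csv_path output files (`NULL` to skip).
#' @return the summary list, invisibly.
#' @export
write_phase_summary <- function(dist, traj, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(dist, "phase_distribution"))
  summary <- list(
    kappa_l4i = dist$fit$kappa,
    psi_l4i_rad = dist$fit$psi,
    gamma_l4i_mean = attr(modulation_series(traj), "mean"),
    n_cycles = dist$n_cycles,
    flags = if (dist$misspecified) "misspecified_unimodal_fit" else character(0))
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(bin_center_rad = dist$histogram$mid,
                 density = dist$histogram$density),
      csv_path, row.names = FALSE)
  }
  invisible(summary)
}

#' Whole-cycle time averages of the order parameters
#'
#' Averages `w_bar` and `w_tilde` over an integer number of drift cycles of
#' the downstream preferred phase (after discarding a transient), removing
#' the partial-cycle bias that contaminates naive segment averages. When the
#' phase does not complete a single cycle (a pinned or fixed-point run) the
#' average is taken over the whole post-transient segment and `n_cycles` is
#' 0.
#'
#' @param traj an `stdp_trajectory`.
#' @param transient_fraction initial fraction of the run discarded.
#' @return list with `w_bar`, `w_tilde`, `n_cycles`.
#' @export
cycle_averages <- function(traj, transient_fraction = 0.5) {
  stopifnot(inherits(traj, "stdp_trajectory"))
  op <- traj$order_params
  op <- op[floor(nrow(op) * transient_fraction):nrow(op), ]
  valid <- !is.na(op$psi)
  if (all(valid)) {
    u <- unwrap_angle(op$psi)
    total <- u[length(u)] - u[1]
    nc <- floor(abs(total) / (2 * pi))
    if (nc >= 1) {
      target <- u[length(u)] - sign(total) * 2 * pi * nc
      first <- if (total > 0) which(u >= target)[1] else which(u <= target)[1]
      op <- op[first:nrow(op), ]
      return(list(w_bar = mean(op$w_bar), w_tilde = mean(op$w_tilde),
                  n_cycles = nc))
    }
  }
  list(w_bar = mean(op$w_bar), w_tilde = mean(op$w_tilde), n_cycles = 0L)
}
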