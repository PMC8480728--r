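#' Upstream thalamic population model
#'
#' `n` whisking neurons firing as independent inhomogeneous Poisson processes
#' whose rate follows the whisking cycle,
#' \deqn{r_k(t) = D\,(1 + \gamma \cos(\nu t - \phi_k)),}
#' with mean rate `D` (spikes/s), modulation depth `gamma` in `[0, 1]`,
#' whisking angular frequency `nu = 2 pi freq_hz` (rad/s), and per-neuron
#' preferred phases `phi_k`. Spikes reach the downstream layer-4 inhibitory
#' neuron after a transmission delay `delay` (s).
#'
#' Preferred phases default to deterministic quantile placement on the
#' upstream von Mises distribution ([place_phases_quantile()]); set
#' `phase_mode = "sample"` for i.i.d. draws (quenched disorder), or pass
#' `phases` directly.
#'
#' @param n number of thalamic neurons.
#' @param rate mean firing rate D, spikes/s.
#' @param gamma modulation depth in `[0, 1]` (`gamma = 1` lets the rate touch
#'   zero once per cycle).
#' @param freq_hz whisking frequency in Hz; stored internally as
#'   `nu = 2*pi*freq_hz` rad/s.
#' @param delay transmission delay d, seconds (non-negative).
#' @param input upstream phase distribution, a [von_mises_spec()].
#' @param phase_mode `"quantile"` (default) or `"sample"`.
#' @param phases optional explicit phase vector (overrides `input`).
#' @param seed seed used when `phase_mode = "sample"`.
#' @return object of class `thalamic_model`.
#' @export
#' @examples
#' thalamic_model(n = 150, rate = 10, gamma = 1, freq_hz = 7, delay = 0.003)
thalamic_model <- function(n = 150, rate = 10, gamma = 1, freq_hz = 7,
                           delay = 0.003,
                           input = von_mises_spec(1, 5 * pi / 6),
                           phase_mode = c("quantile", "sample"),
                           phases = NULL, seed = NULL) {
  phase_mode <- match.arg(phase_mode)
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  if (rate <= 0) abort("`rate` must be positive.")
  if (gamma < 0 || gamma > 1) {
    abort("`gamma` must lie in [0, 1] so the rate stays non-negative.",
          class = "whiskstdp_invalid_parameter")
  }
  if (delay < 0) abort("`delay` must be non-negative.")
  if (freq_hz < 0) abort("`freq_hz` must be non-negative.")
  if (is.null(phases)) {
    phases <- switch(phase_mode,
      quantile = place_phases_quantile(input, n),
      sample = sample_phases_accept_reject(input, n, seed = seed))
  } else {
    if (length(phases) != n) abort("`phases` must have length `n`.")
    phases <- wrap_angle(phases)
  }
  structure(
    list(n = as.integer(n), rate = rate, gamma = gamma,
         nu = 2 * pi * freq_hz, freq_hz = freq_hz, delay = delay,
         input = input, phase_mode = phase_mode, phases = phases),
    class = "thalamic_model")
}

#' @export
print.thalamic_model <- function(x, ...) {
  cat(sprintf(
    "<thalamic model> N = %d, D = %g spikes/s, gamma = %g, whisking %g Hz, delay %g ms\n",
    x$n, x$rate, x$gamma, x$freq_hz, 1000 * x$delay))
  cat(sprintf("  input phases: kappa = %g, psi = %g rad (%s)\n",
              x$input$kappa, x$input$psi, x$phase_mode))
  invisible(x)
}

#' Instantaneous thalamic firing rate
#'
#' @param model a [thalamic_model()].
#' @param k neuron index (1-based).
#' @param t time, seconds (vectorized).
#' @return rate in spikes/s.
#' @export
thalamic_rate <- function(model, k, t) {
  stopifnot(inherits(model, "thalamic_model"))
  if (k < 1 || k > model$n) abort("neuron index out of range.")
  model$rate * (1 + model$gamma * cos(model$nu * t - model$phases[k]))
}

#' Order parameters of a synaptic weight profile
#'
#' The mean weight and the first circular Fourier component of the profile
#' over the preferred phases,
#' \deqn{\bar w = \frac1N \sum_k w_k, \qquad
#'       \tilde w e^{i\psi} = \frac1N \sum_k w_k e^{i\phi_k},}
#' with \eqn{\tilde w \ge 0}. When the first component vanishes (below
#' 1e-12) the phase `psi` is undefined and flagged, never silently NaN.
#'
#' @param weights numeric vector of synaptic weights in `[0, 1]`.
#' @param phases numeric vector of preferred phases, same length.
#' @return list with `w_bar`, `w_tilde`, `psi` (NA when undefined) and
#'   `psi_defined`.
#' @export
order_parameters <- function(weights, phases) {
  if (length(weights) == 0) abort("empty weight profile.")
  if (length(weights) != length(phases)) abort("length mismatch.")
  if (any(weights < -1e-12 | weights > 1 + 1e-12)) {
    abort("weights must lie in [0, 1].")
  }
  w_bar <- mean(weights)
  z <- mean(weights * exp(1i * phases))
  w_tilde <- Mod(z)
  defined <- w_tilde > 1e-12
  list(w_bar = w_bar,
       w_tilde = w_tilde,
       psi = if (defined) wrap_angle(Arg(z)) else NA_real_,
       psi_defined = defined)
}

#' Rhythmic tuning of the downstream neuron
#'
#' The linear-Poisson downstream neuron inherits rhythmic tuning from the
#' weighted pool: mean rate `D_l4i = D * w_bar`, modulation depth
#' `gamma_l4i = gamma * w_tilde / w_bar`, preferred phase
#' `psi_l4i = psi + nu * d` (wrapped).
#'
#' @param op order parameters from [order_parameters()].
#' @param model a [thalamic_model()].
#' @return list with `d_l4i`, `gamma_l4i`, `psi_l4i` (NA when the profile has
#'   no first Fourier component).
#' @export
downstream_tuning <- function(op, model) {
  stopifnot(inherits(model, "thalamic_model"))
  if (op$w_bar < 0) abort("w_bar must be non-negative.")
  if (op$w_bar == 0 && op$w_tilde > 1e-12) {
    abort("invariant violation: w_tilde > 0 with w_bar = 0.")
  }
  gamma_l4i <- if (op$w_bar == 0) 0 else model$gamma * op$w_tilde / op$w_bar
  list(
    d_l4i = model$rate * op$w_bar,
    gamma_l4i = gamma_l4i,
    psi_l4i = if (isTRUE(op$psi_defined))
      wrap_angle(op$psi + model$nu * model$delay) else NA_real_)
}
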