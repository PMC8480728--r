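#' Generate thalamic spike trains
#'
#' Independent inhomogeneous Poisson trains per neuron, realized by thinning
#' a homogeneous train of rate `D (1 + gamma)`.
#'
#' @param model a [thalamic_model()].
#' @param duration simulated time window, seconds (spikes on
#'   `[t_start, t_start + duration)`).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param t_start window start, seconds (default 0).
#' @return tibble with columns `neuron` (integer) and `time` (seconds),
#'   sorted by neuron then time.
#' @export
#' @examples
#' m <- thalamic_model(n = 5)
#' generate_thalamic_spikes(m, duration = 2, seed = 1)
generate_thalamic_spikes <- function(model, duration, seed = NULL, t_start = 0) {
  stopifnot(inherits(model, "thalamic_model"), duration > 0)
  gen <- function() {
    bound <- model$rate * (1 + model$gamma)
    n_prop <- rpois(model$n, bound * duration)
    neuron <- rep(seq_len(model$n), n_prop)
    t <- t_start + runif(sum(n_prop), 0, duration)
    accept <- runif(sum(n_prop)) <
      (1 + model$gamma * cos(model$nu * t - model$phases[neuron])) /
      (1 + model$gamma)
    out <- tibble(neuron = neuron[accept], time = t[accept])
    dplyr::arrange(out, .data$neuron, .data$time)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Downstream spikes of the linear-Poisson neuron
#'
#' The downstream rate is a weighted sum of delayed pre-synaptic delta
#' functions, so each thalamic spike of neuron `k` at time `t` elicits a
#' downstream spike at `t + d` with probability `w_k / N`.
#'
#' @param spikes tibble from [generate_thalamic_spikes()].
#' @param weights synaptic weight vector (length `model$n`, in `[0, 1]`).
#' @param model a [thalamic_model()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return sorted numeric vector of downstream spike times, seconds.
#' @export
downstream_spikes <- function(spikes, weights, model, seed = NULL) {
  stopifnot(inherits(model, "thalamic_model"), length(weights) == model$n)
  check_weight_domain(weights)
  gen <- function() {
    keep <- runif(nrow(spikes)) < weights[spikes$neuron] / model$n
    sort(spikes$time[keep] + model$delay)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Apply the STDP rule to a window of spikes
#'
#' Every (pre, post) pair with `|t_post - t_pre|` up to `10 * max(tau)`
#' contributes additively; contributions are accumulated at the pre-update
#' weights and applied in one batch (first order in the learning rate, the
#' regime the slow-learning theory describes), then clamped to `[0, 1]`.
#'
#' @param spikes pre-synaptic tibble (`neuron`, `time`), sorted by time
#'   within neuron.
#' @param post_times sorted numeric vector of downstream spike times.
#' @param rule an [stdp_rule()].
#' @param weights current weight vector.
#' @param n_neurons number of pre-synaptic neurons.
#' @return updated weight vector.
#' @export
apply_stdp_window <- function(spikes, post_times, rule, weights,
                              n_neurons = length(weights)) {
  stopifnot(inherits(rule, "stdp_rule"))
  check_weight_domain(weights)
  if (length(post_times) == 0 || nrow(spikes) == 0) return(weights)
  sums <- stdp_pair_sums(
    pre_times = spikes$time, pre_id = as.integer(spikes$neuron),
    n_neurons = as.integer(n_neurons), post_times = post_times,
    tau_plus = rule$tau_plus, tau_minus = rule$tau_minus,
    symmetric = rule$family == "symmetric_gaussian",
    trunc = 10 * max(rule$tau_plus, rule$tau_minus))
  dw <- rule$lambda * (f_plus(weights, rule$mu) * sums[, 1] -
                         f_minus(weights, rule$mu, rule$alpha) * sums[, 2])
  pmin(1, pmax(0, weights + dw))
}

#' Event-level spiking STDP simulation
#'
#' The validation oracle for the mean-field dynamics: alternating windows of
#' spike generation with frozen weights and batched STDP application.
#' Spike pairs that straddle a window boundary are counted exactly once (the
#' previous window's tail, within the pair-truncation horizon, is carried
#' over); with the weakly nonlinear weight dependence used here
#' (`mu` of order 0.01) even sub-percent biases in the pair statistics are
#' amplified, so this bookkeeping matters.
#'
#' @param model a [thalamic_model()].
#' @param rule an [stdp_rule()] (its `lambda` sets the real-time duration
#'   `duration = s_total / lambda`).
#' @param s_total total rescaled time `s = lambda * t` to simulate.
#' @param window_cycles batch window length in whisking cycles (default 10;
#'   the batch acts as one effective integration step of rescaled size
#'   `lambda * window_cycles / freq_hz`, which must stay small enough to
#'   resolve the weight dynamics).
#' @param init initial weights; `NULL` draws i.i.d. uniform (0.3, 0.7).
#' @param seed integer seed (controls the initial condition draw and all
#'   spike randomness).
#' @return an `stdp_trajectory` (order parameters recorded once per window;
#'   `time` in rescaled units).
#' @export
run_spiking_simulation <- function(model, rule, s_total, window_cycles = 10,
                                   init = NULL, seed = NULL) {
  stopifnot(inherits(model, "thalamic_model"), inherits(rule, "stdp_rule"))
  if (model$freq_hz <= 0) abort("spiking simulation needs a positive whisking frequency.")
  t_window <- window_cycles / model$freq_hz
  if (rule$lambda * t_window > 0.5) {
    warn("batch window is large on the rescaled time axis; consider a smaller lambda or window.")
  }
  n_windows <- max(1L, as.integer(round(s_total / rule$lambda / t_window)))
  trunc <- 10 * max(rule$tau_plus, rule$tau_minus)
  if (t_window < trunc) abort("window must exceed the pair-truncation horizon.")
  run <- function() {
    w0 <- if (is.null(init)) runif(model$n, 0.3, 0.7) else init
    check_weight_domain(w0)
    res <- spiking_run_core(
      w0 = w0, phases = model$phases,
      D = model$rate, gamma_mod = model$gamma, nu = model$nu,
      delay = model$delay, tau_plus = rule$tau_plus,
      tau_minus = rule$tau_minus, mu = rule$mu, alpha = rule$alpha,
      lambda = rule$lambda, symmetric = rule$family == "symmetric_gaussian",
      n_windows = n_windows, t_window = t_window, trunc = trunc)
    structure(
      list(order_params = tibble(time = res$time, w_bar = res$w_bar,
                                 w_tilde = res$w_tilde, psi = res$psi),
           w_final = res$w_final, init = w0, model = model, rule = rule,
           window_cycles = window_cycles, s_total = s_total,
           record_every = 1, kind = "spiking"),
      class = "stdp_trajectory")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write spike trains to CSV
#'
#' Two columns, `neuron_id` and `time_s`.
#'
#' @param spikes tibble from [generate_thalamic_spikes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  utils::write.csv(
    data.frame(neuron_id = spikes$neuron, time_s = spikes$time),
    path, row.names = FALSE)
  invisible(path)
}
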