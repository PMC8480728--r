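#' Tidy an STDP trajectory
#'
#' @param x an `stdp_trajectory`.
#' @param ... unused.
#' @return tibble with `time` (rescaled units), `w_bar`, `w_tilde`, `psi`,
#'   and `psi_l4i` (delay-shifted downstream phase).
#' @export
tidy.stdp_trajectory <- function(x, ...) {
  dplyr::mutate(x$order_params,
                psi_l4i = wrap_angle(.data$psi + x$model$nu * x$model$delay))
}

#' @rdname tidy.stdp_trajectory
#' @return for `glance()`: one row with the run settings and final state.
#' @export
glance.stdp_trajectory <- function(x, ...) {
  op <- x$order_params
  n <- nrow(op)
  tibble(
    kind = x$kind,
    n_neurons = x$model$n,
    n_recorded = n,
    s_end = op$time[n],
    w_bar_final = op$w_bar[n],
    w_tilde_final = op$w_tilde[n],
    psi_final = op$psi[n])
}

#' Tidy a phase distribution
#'
#' @param x a `phase_distribution`.
#' @param ... unused.
#' @return tibble of histogram bins: `mid`, `density`, `fitted` (the fitted
#'   von Mises density at the bin center).
#' @export
tidy.phase_distribution <- function(x, ...) {
  dplyr::mutate(x$histogram, fitted = von_mises_density(x$fit, .data$mid))
}

#' @rdname tidy.phase_distribution
#' @export
glance.phase_distribution <- function(x, ...) {
  tibble(kappa = x$fit$kappa, psi = x$fit$psi,
         n_cycles = x$n_cycles, n_samples = x$n_samples,
         fit_method = x$fit_method, misspecified = x$misspecified,
         sup_distance = x$sup_distance)
}

#' Tidy a mean-field fixed point
#'
#' @param x an `stdp_fixed_point`.
#' @param ... unused.
#' @return the profile tibble (`phi`, `w`).
#' @export
tidy.stdp_fixed_point <- function(x, ...) x$profile

#' @rdname tidy.stdp_fixed_point
#' @export
glance.stdp_fixed_point <- function(x, ...) {
  tibble(w_bar = x$w_bar, w_tilde = x$w_tilde, psi = x$psi,
         converged = x$converged, iterations = x$iterations,
         residual = x$residual, residual_with_fd = x$residual_with_fd)
}

#' Tidy a pooling ensemble
#'
#' @param x a `pooling_ensemble`.
#' @param ... unused.
#' @return tibble with one row per repetition: `rep`, `phase`.
#' @export
tidy.pooling_ensemble <- function(x, ...) {
  tibble(rep = seq_along(x$phases), phase = x$phases)
}

#' @rdname tidy.pooling_ensemble
#' @export
glance.pooling_ensemble <- function(x, ...) {
  tibble(mode = x$mode, n = x$n, reps = x$reps,
         kappa_l4i = x$fit$kappa, psi_l4i = x$fit$psi,
         input_kappa = x$input$kappa, input_psi = x$input$psi)
}
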