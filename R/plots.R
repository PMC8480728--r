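#' Plot an STDP trajectory
#'
#' Order parameters (`w_bar`, `w_tilde`) and the downstream preferred phase
#' against rescaled time.
#'
#' @param object an `stdp_trajectory`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stdp_trajectory <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    dplyr::select(df, "time", "w_bar", "w_tilde", "psi_l4i"),
    -"time", names_to = "series", values_to = "value")
  long$series <- factor(long$series,
                        levels = c("w_bar", "w_tilde", "psi_l4i"),
                        labels = c("mean weight", "first Fourier magnitude",
                                   "downstream phase [rad]"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "rescaled time s = λ t", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase distribution with its von Mises fit
#'
#' @param object a `phase_distribution`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.phase_distribution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density),
                      width = 2 * pi / object$n_bins,
                      fill = "grey70", colour = "grey40", linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "downstream preferred phase [rad]", y = "density",
                  subtitle = sprintf("von Mises fit: κ = %.2f, ψ = %.2f rad",
                                     object$fit$kappa, object$fit$psi)) +
    ggplot2::theme_minimal()
}

#' Plot a mean-field fixed-point profile
#'
#' @param object an `stdp_fixed_point`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stdp_fixed_point <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$phi, y = .data$w)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "preferred phase φ [rad]", y = "stationary weight w*(φ)") +
    ggplot2::theme_minimal()
}

#' Plot a pooling ensemble
#'
#' Histogram of the downstream preferred phases across repetitions with the
#' fitted von Mises density.
#'
#' @param object a `pooling_ensemble`.
#' @param n_bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pooling_ensemble <- function(object, n_bins = 36, ...) {
  h <- weighted_phase_histogram(object$phases, rep(1, length(object$phases)),
                                n_bins)
  h$fitted <- von_mises_density(object$fit, h$mid)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density), width = 2 * pi / n_bins,
                      fill = "grey70", colour = "grey40", linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "pooled preferred phase [rad]", y = "density",
                  subtitle = sprintf("%s pooling, N = %d: κ = %.2f",
                                     object$mode, object$n, object$fit$kappa)) +
    ggplot2::theme_minimal()
}
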