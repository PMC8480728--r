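#' STDP learning rule
#'
#' Pairwise-additive spike-timing-dependent plasticity: every pre/post spike
#' pair with lag `dt = t_post - t_pre` contributes
#' \deqn{\Delta w = \lambda\,[f_+(w) K_+(\Delta t) - f_-(w) K_-(\Delta t)],}
#' with weight-dependence factors \eqn{f_+(w) = (1-w)^\mu},
#' \eqn{f_-(w) = \alpha w^\mu} (Guetig-style soft bounds keeping weights in
#' `[0, 1]`) and one of two normalized temporal kernel families:
#'
#' * `"asymmetric_exponential"`: causal potentiation / anti-causal depression,
#'   \eqn{K_\pm(\Delta t) = e^{\mp\Delta t/\tau_\pm}/\tau_\pm\,
#'   \Theta(\pm \Delta t)};
#' * `"symmetric_gaussian"`: centred Gaussians of widths \eqn{\tau_\pm}
#'   (only the absolute lag matters).
#'
#' `mu` in `[0, 1]` controls the nonlinearity (`mu = 0` is the additive rule
#' with `f_+ = 1`, `f_- = alpha`), `alpha > 0` the relative strength of
#' depression, and `lambda > 0` the learning rate.
#'
#' @param family kernel family.
#' @param tau_plus,tau_minus kernel time constants, seconds (positive).
#'   Depression windows are typically reported longer than potentiation
#'   windows; a shorter `tau_minus` is allowed but warned about.
#' @param mu weight-dependence exponent in `[0, 1]`.
#' @param alpha relative depression strength, positive.
#' @param lambda learning rate, positive.
#' @return object of class `stdp_rule`.
#' @export
#' @examples
#' stdp_rule("asymmetric_exponential", tau_plus = 0.022, tau_minus = 0.050)
stdp_rule <- function(family = c("asymmetric_exponential", "symmetric_gaussian"),
                      tau_plus = 0.022, tau_minus = 0.050,
                      mu = 0.01, alpha = 1.1, lambda = 0.01) {
  family <- match.arg(family)
  if (tau_plus <= 0 || tau_minus <= 0) abort("kernel time constants must be positive.")
  if (mu < 0 || mu > 1) abort("`mu` must lie in [0, 1].")
  if (alpha <= 0) abort("`alpha` must be positive.")
  if (lambda <= 0) abort("`lambda` must be positive.")
  if (tau_minus <= tau_plus) {
    warn("tau_minus <= tau_plus: depression window not longer than potentiation window.")
  }
  structure(list(family = family, tau_plus = tau_plus, tau_minus = tau_minus,
                 mu = mu, alpha = alpha, lambda = lambda),
            class = "stdp_rule")
}

#' @export
print.stdp_rule <- function(x, ...) {
  cat(sprintf(
    "<STDP rule> %s: tau+ = %g ms, tau- = %g ms, mu = %g, alpha = %g, lambda = %g\n",
    x$family, 1000 * x$tau_plus, 1000 * x$tau_minus, x$mu, x$alpha, x$lambda))
  invisible(x)
}

#' Weight-dependence factors
#'
#' `f_plus(w) = (1 - w)^mu`, `f_minus(w) = alpha * w^mu`. At `mu = 0` both
#' take their additive-rule limit (1 and `alpha`) across all of `[0, 1]`.
#'
#' @param w weights in `[0, 1]` (vectorized).
#' @param mu exponent in `[0, 1]`.
#' @param alpha relative depression strength.
#' @return non-negative numeric vector.
#' @export
f_plus <- function(w, mu) {
  check_weight_domain(w)
  if (mu == 0) rep(1, length(w)) else (1 - w)^mu
}

#' @rdname f_plus
#' @export
f_minus <- function(w, mu, alpha) {
  check_weight_domain(w)
  if (mu == 0) rep(alpha, length(w)) else alpha * w^mu
}

check_weight_domain <- function(w) {
  if (any(w < 0 | w > 1)) {
    abort("weights must lie in [0, 1].", class = "whiskstdp_domain_error")
  }
  invisible(w)
}

#' Temporal kernel value
#'
#' Each branch is a normalized density over the lag `dt = t_post - t_pre`.
#' A lag of exactly zero contributes to neither branch of the asymmetric
#' kernel (measure zero for continuous spike times; avoids double counting).
#'
#' @param rule an [stdp_rule()].
#' @param branch `"+"` (potentiation) or `"-"` (depression).
#' @param dt lag(s), seconds.
#' @return kernel density values, 1/s.
#' @export
kernel_value <- function(rule, branch = c("+", "-"), dt) {
  stopifnot(inherits(rule, "stdp_rule"))
  branch <- match.arg(branch)
  tau <- if (branch == "+") rule$tau_plus else rule$tau_minus
  if (rule$family == "asymmetric_exponential") {
    s <- if (branch == "+") 1 else -1
    ifelse(s * dt > 0, exp(-s * dt / tau) / tau, 0)
  } else {
    exp(-0.5 * (dt / tau)^2) / (tau * sqrt(2 * pi))
  }
}

#' Kernel Fourier transforms at the whisking frequency
#'
#' \deqn{\tilde K_\pm e^{i\Omega_\pm} = \int K_\pm(\Delta)\,
#'   e^{-i\nu\Delta}\, d\Delta.}
#' Closed forms: for the asymmetric exponential family
#' \eqn{\tilde K_\pm = (1 + (\nu\tau_\pm)^2)^{-1/2}},
#' \eqn{\Omega_+ = -\arctan(\nu\tau_+)}, \eqn{\Omega_- = +\arctan(\nu\tau_-)};
#' for the symmetric Gaussian family \eqn{\tilde K_\pm = e^{-(\nu\tau_\pm)^2/2}},
#' \eqn{\Omega_\pm = 0}. The zeroth moments are 1 by construction (normalized
#' kernels).
#'
#' @param rule an [stdp_rule()].
#' @param nu angular frequency, rad/s (non-negative).
#' @return list with `k_bar_plus`, `k_bar_minus` (both 1), magnitudes
#'   `k_tilde_plus`, `k_tilde_minus`, phases `omega_plus`, `omega_minus`
#'   (wrapped), and `nu`.
#' @export
kernel_fourier <- function(rule, nu) {
  stopifnot(inherits(rule, "stdp_rule"), nu >= 0)
  if (rule$family == "asymmetric_exponential") {
    ktp <- 1 / sqrt(1 + (nu * rule$tau_plus)^2)
    ktm <- 1 / sqrt(1 + (nu * rule$tau_minus)^2)
    op <- -atan(nu * rule$tau_plus)
    om <- atan(nu * rule$tau_minus)
  } else {
    ktp <- exp(-0.5 * (nu * rule$tau_plus)^2)
    ktm <- exp(-0.5 * (nu * rule$tau_minus)^2)
    op <- 0
    om <- 0
  }
  list(k_bar_plus = 1, k_bar_minus = 1,
       k_tilde_plus = ktp, k_tilde_minus = ktm,
       omega_plus = wrap_angle(op), omega_minus = wrap_angle(om),
       nu = nu)
}
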