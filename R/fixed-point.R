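#' Fixed-point weight profile from a guess of the order parameters
#'
#' In the continuum limit the stationary profile satisfies
#' \deqn{w^*(\phi) = \left(1 + \alpha^{1/\mu}
#'   \left(\frac{1 + X_-}{1 + X_+}\right)^{1/\mu}\right)^{-1},
#'   \quad X_\pm = \frac{\tilde w}{\bar w}\frac{\gamma^2}{2}\tilde K_\pm
#'   \cos(\phi - \nu d - \Omega_\pm - \psi).}
#'
#' @param op order parameters (`w_bar > 0`; `psi` used only when defined).
#' @param rule an [stdp_rule()] (`mu > 0`; the additive rule has no interior
#'   fixed point).
#' @param model a [thalamic_model()].
#' @param phi phase grid, radians.
#' @return numeric vector `w*(phi)` in `[0, 1]`.
#' @export
profile_from_order_params <- function(op, rule, model, phi) {
  stopifnot(inherits(rule, "stdp_rule"), inherits(model, "thalamic_model"))
  if (op$w_bar <= 0) abort("fixed-point profile needs w_bar > 0.")
  if (rule$mu <= 0) abort("`mu` must be positive for the stationary profile.")
  kf <- kernel_fourier(rule, model$nu)
  psi <- if (isTRUE(op$psi_defined)) op$psi else 0
  ratio <- op$w_tilde / op$w_bar * model$gamma^2 / 2
  xp <- ratio * kf$k_tilde_plus * cos(phi - model$nu * model$delay - kf$omega_plus - psi)
  xm <- ratio * kf$k_tilde_minus * cos(phi - model$nu * model$delay - kf$omega_minus - psi)
  if (any(1 + xp <= 0)) {
    abort("non-physical guess: 1 + X+ <= 0 on the grid.",
          class = "whiskstdp_domain_error")
  }
  # log-space keeps alpha^(1/mu) finite for small mu
  1 / (1 + exp(log(rule$alpha) / rule$mu +
                 (log1p(xm) - log1p(xp)) / rule$mu))
}

#' Self-consistent mean-field fixed point
#'
#' Damped fixed-point iteration: from a guess of the order parameters,
#' build the stationary profile ([profile_from_order_params()]), recompute
#' the order parameters by quadrature against the upstream von Mises density
#' on a uniform periodic grid (trapezoid rule, spectrally accurate), and
#' repeat until the order parameters stop moving. The phase is updated
#' through the complex first Fourier component, so no 2*pi jumps occur.
#' Existence only: stability is assessed empirically by integrating the
#' dynamics from a perturbed solution.
#'
#' @inheritParams profile_from_order_params
#' @param init optional initial `(w_bar, w_tilde, psi)` guess list; default
#'   starts from the uniform balance point with a small rhythmic seed.
#' @param damping update damping in (0, 1]; default 0.5.
#' @param tol convergence tolerance on the order parameters.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE` rather than an error.
#' @param n_grid phase-grid size (default 512).
#' @return object of class `stdp_fixed_point`: tibble `profile`
#'   (`phi`, `w`), the order parameters, `converged`, `iterations`, and the
#'   max |RHS| residuals of the continuum dynamics with and without the
#'   finite-N delay term.
#' @export
solve_self_consistent <- function(rule, model, init = NULL, damping = 0.5,
                                  tol = 1e-10, max_iter = 500, n_grid = 512) {
  stopifnot(inherits(rule, "stdp_rule"), inherits(model, "thalamic_model"))
  phi <- seq(-pi, pi, length.out = n_grid + 1)[seq_len(n_grid)]
  pr <- von_mises_density(model$input, phi)
  dphi <- 2 * pi / n_grid
  quad_ops <- function(w) {
    w_bar <- sum(pr * w) * dphi
    z <- sum(pr * w * exp(1i * phi)) * dphi
    list(w_bar = w_bar, w_tilde = Mod(z),
         psi = if (Mod(z) > 1e-12) Arg(z) else NA_real_,
         psi_defined = Mod(z) > 1e-12, z = z)
  }
  if (is.null(init)) {
    w_unif <- 1 / (1 + exp(log(rule$alpha) / rule$mu))
    cur <- list(w_bar = w_unif, w_tilde = 0.1 * w_unif,
                psi = model$input$psi, psi_defined = TRUE)
  } else {
    cur <- init
    cur$psi_defined <- isTRUE(cur$psi_defined) || (!is.null(cur$psi) && !is.na(cur$psi))
  }
  z_cur <- cur$w_tilde * exp(1i * (if (isTRUE(cur$psi_defined)) cur$psi else 0))
  converged <- FALSE
  iter <- 0
  w <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    w <- profile_from_order_params(cur, rule, model, phi)
    nxt <- quad_ops(w)
    new_wbar <- (1 - damping) * cur$w_bar + damping * nxt$w_bar
    new_z <- (1 - damping) * z_cur + damping * nxt$z
    delta <- abs(new_wbar - cur$w_bar) + Mod(new_z - z_cur)
    cur <- list(w_bar = new_wbar, w_tilde = Mod(new_z),
                psi = if (Mod(new_z) > 1e-12) Arg(new_z) else NA_real_,
                psi_defined = Mod(new_z) > 1e-12)
    z_cur <- new_z
    if (delta < tol) { converged <- TRUE; break }
  }
  w <- profile_from_order_params(cur, rule, model, phi)
  res <- fp_residual(w, phi, cur, rule, model)
  structure(
    list(profile = tibble(phi = phi, w = w),
         w_bar = cur$w_bar, w_tilde = cur$w_tilde, psi = wrap_angle(cur$psi),
         converged = converged, iterations = iter,
         residual = res$without_fd, residual_with_fd = res$with_fd,
         rule = rule, model = model, n_grid = n_grid),
    class = "stdp_fixed_point")
}

# max |RHS| of the continuum dynamics at a candidate profile, with and
# without the finite-N delay term
fp_residual <- function(w, phi, op, rule, model) {
  kf <- kernel_fourier(rule, model$nu)
  fp <- f_plus(w, rule$mu)
  fm <- f_minus(w, rule$mu, rule$alpha)
  psi <- if (isTRUE(op$psi_defined)) op$psi else 0
  nud <- model$nu * model$delay
  f0 <- model$rate^2 * (fp - fm)
  f1 <- model$rate^2 * model$gamma^2 / 2 *
    (kf$k_tilde_plus * fp * cos(phi - kf$omega_plus - nud - psi) -
       kf$k_tilde_minus * fm * cos(phi - kf$omega_minus - nud - psi))
  fd <- w * (model$rate / model$n) *
    (fp * kernel_value(rule, "+", model$delay) -
       fm * kernel_value(rule, "-", model$delay))
  rhs0 <- op$w_bar * f0 + op$w_tilde * f1
  list(without_fd = max(abs(rhs0)), with_fd = max(abs(rhs0 + fd)))
}

#' @export
print.stdp_fixed_point <- function(x, ...) {
  cat(sprintf(
    "<mean-field fixed point> %s after %d iterations\n",
    if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  w_bar = %.6f, w_tilde = %.6f, psi = %.4f rad\n",
              x$w_bar, x$w_tilde, x$psi))
  cat(sprintf("  residual (continuum) = %.3g, with finite-N term = %.3g\n",
              x$residual, x$residual_with_fd))
  invisible(x)
}

#' Write a fixed-point result to disk
#'
#' JSON summary (order parameters, residuals, convergence) plus a CSV of the
#' profile (`phi`, `w`).
#'
#' @param x an `stdp_fixed_point`.
#' @param json_path,csv_path output files (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_fixed_point <- function(x, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(x, "stdp_fixed_point"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(w_bar = x$w_bar, w_tilde = x$w_tilde, psi = x$psi,
           converged = x$converged, iterations = x$iterations,
           residual = x$residual, residual_with_fd = x$residual_with_fd),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) utils::write.csv(x$profile, csv_path, row.names = FALSE)
  invisible(x)
}

#' Empirical stability probe of a fixed point
#'
#' Existence and stability are separate questions: the solver only
#' establishes existence. This perturbs the converged profile, integrates
#' the continuum dynamics, and reports whether the order parameters return
#' to the fixed point.
#'
#' @param fp an `stdp_fixed_point`.
#' @param amplitude perturbation amplitude on the weights (default 0.05).
#' @param s_total rescaled integration time (default 20).
#' @param tol return tolerance on the order parameters.
#' @param seed seed for the random perturbation.
#' @return logical: did the perturbed trajectory return to the fixed point?
#' @export
fixed_point_stable <- function(fp, amplitude = 0.05, s_total = 20,
                               tol = 1e-3, seed = 1) {
  stopifnot(inherits(fp, "stdp_fixed_point"))
  model <- fp$model
  w_star <- approx(fp$profile$phi, fp$profile$w, xout = model$phases,
                   rule = 2)$y
  pert <- withr::with_seed(seed, runif(model$n, -amplitude, amplitude))
  init <- pmin(1, pmax(0, w_star + pert))
  traj <- euler_integrate(model, fp$rule, init = init,
                          n_steps = round(s_total / (fp$rule$lambda * 0.1)),
                          dt = 0.1, include_fd = FALSE)
  op <- order_parameters(traj$w_final, model$phases)
  abs(op$w_bar - fp$w_bar) < tol && abs(op$w_tilde - fp$w_tilde) < tol &&
    (!op$psi_defined || abs(circ_diff(op$psi, fp$psi)) < 10 * tol)
}
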