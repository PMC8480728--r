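#' Cross-correlation between two pre-synaptic neurons
#'
#' For inhomogeneous Poisson neurons locked to the whisking cycle the
#' pairwise cross-correlation at lag `dt` splits into a smooth rhythmic part,
#' \deqn{D^2\left(1 + \frac{\gamma^2}{2}\cos(\nu\Delta t + \phi_j -
#'   \phi_k)\right),}
#' plus, for the autocorrelation (`j == k`), a Poisson atom `D * delta(dt)`.
#' The atom is returned as a separate weight, never folded into the smooth
#' part.
#'
#' @param model a [thalamic_model()].
#' @param j,k neuron indices (1-based).
#' @param dt lag(s), seconds.
#' @return list with `smooth` (rate^2, vectorized over `dt`) and
#'   `delta_weight` (the mass of the `delta(dt)` atom: `D` when `j == k`,
#'   else 0).
#' @export
cross_corr_pre_pre <- function(model, j, k, dt) {
  stopifnot(inherits(model, "thalamic_model"))
  if (j < 1 || j > model$n || k < 1 || k > model$n) abort("index out of range.")
  smooth <- model$rate^2 *
    (1 + model$gamma^2 / 2 *
       cos(model$nu * dt + model$phases[j] - model$phases[k]))
  list(smooth = smooth, delta_weight = if (j == k) model$rate else 0)
}

#' Cross-correlation between a pre-synaptic neuron and the downstream neuron
#'
#' Linearity of the downstream neuron makes this the weight-averaged
#' pre-pre correlation at lag `dt - d`:
#' \deqn{\Gamma_{j,\mathrm{post}}(\Delta t) = \frac{D}{N} w_j
#'   \delta(\Delta t - d) + D^2\left(\bar w + \frac{\gamma^2}{2} \tilde w
#'   \cos(\nu(\Delta t - d) + \phi_j - \psi)\right).}
#'
#' @param j pre-synaptic neuron index.
#' @param weights synaptic weight vector.
#' @param op order parameters of `weights` (see [order_parameters()]).
#' @param model a [thalamic_model()].
#' @param dt lag(s), seconds.
#' @return list with `smooth` (vectorized over `dt`), `delta_weight_at_d`
#'   (`w_j D / N`) and `delta_time` (the delay `d`).
#' @export
cross_corr_pre_post <- function(j, weights, op, model, dt) {
  stopifnot(inherits(model, "thalamic_model"))
  if (j < 1 || j > model$n) abort("index out of range.")
  psi <- if (isTRUE(op$psi_defined)) op$psi else 0  # multiplied by w_tilde ~ 0
  smooth <- model$rate^2 *
    (op$w_bar + model$gamma^2 / 2 * op$w_tilde *
       cos(model$nu * (dt - model$delay) + model$phases[j] - psi))
  list(smooth = smooth,
       delta_weight_at_d = weights[j] * model$rate / model$n,
       delta_time = model$delay)
}

#' Continuum drift terms of the mean-field dynamics
#'
#' The three per-synapse components of the slow-learning weight velocity:
#' the finite-N delay-atom term `f_d` (carrying the 1/N prefactor), the
#' phase-independent term `f_0`, and the rhythmic term `f_1` that couples
#' each synapse's phase to the profile's first Fourier component.
#'
#' @inheritParams cross_corr_pre_post
#' @param phases preferred-phase vector aligned with `weights`.
#' @param rule an [stdp_rule()].
#' @return tibble with columns `phase`, `weight`, `f_d`, `f_0`, `f_1`.
#' @export
drift_terms <- function(weights, phases, op, rule, model) {
  stopifnot(inherits(rule, "stdp_rule"), inherits(model, "thalamic_model"))
  check_weight_domain(weights)
  kf <- kernel_fourier(rule, model$nu)
  fp <- f_plus(weights, rule$mu)
  fm <- f_minus(weights, rule$mu, rule$alpha)
  psi <- if (isTRUE(op$psi_defined)) op$psi else 0
  nud <- model$nu * model$delay
  kp_d <- kernel_value(rule, "+", model$delay)
  km_d <- kernel_value(rule, "-", model$delay)
  tibble(
    phase = phases,
    weight = weights,
    f_d = weights * (model$rate / model$n) * (fp * kp_d - fm * km_d),
    f_0 = model$rate^2 * (kf$k_bar_plus * fp - kf$k_bar_minus * fm),
    f_1 = model$rate^2 * model$gamma^2 / 2 *
      (kf$k_tilde_plus * fp * cos(phases - kf$omega_plus - nud - psi) -
         kf$k_tilde_minus * fm * cos(phases - kf$omega_minus - nud - psi)))
}

#' Mean-field weight velocity
#'
#' Right-hand side of the slow-learning dynamics in rescaled time
#' `s = lambda * t`:
#' \deqn{\dot w(\phi)/\lambda = F_d + \bar w F_0 + \tilde w F_1.}
#'
#' @inheritParams drift_terms
#' @param include_fd include the finite-N delay-atom term (default TRUE);
#'   `FALSE` realizes the strict continuum limit.
#' @return numeric weight-velocity vector (per unit rescaled time).
#' @export
meanfield_rhs <- function(weights, phases, rule, model, include_fd = TRUE) {
  op <- order_parameters(weights, phases)
  dt <- drift_terms(weights, phases, op, rule, model)
  (if (include_fd) dt$f_d else 0) + op$w_bar * dt$f_0 + op$w_tilde * dt$f_1
}

#' Integrate the mean-field STDP dynamics
#'
#' Explicit Euler on the rescaled time `s = lambda * t`; the step in `s` is
#' `rule$lambda * dt`, so the conventional bookkeeping (step `dt = 0.1` with
#' `lambda = 0.01`) gives `ds = 1e-3`. Weights are clamped to `[0, 1]` after
#' every step (with `mu > 0` the interior is attracting, so the clamp is a
#' numerical guard only). All distribution-level results are invariant to
#' jointly rescaling `lambda` and `dt`; only the nominal trajectory speed
#' changes.
#'
#' @param model a [thalamic_model()].
#' @param rule an [stdp_rule()].
#' @param init initial weights: a numeric vector of length `model$n`, or
#'   `NULL` to draw i.i.d. uniform on (0.3, 0.7) using `seed`.
#' @param n_steps number of Euler steps.
#' @param dt Euler step in unscaled time units (default 0.1; the rescaled
#'   step is `rule$lambda * dt`).
#' @param record_every record the order parameters every this many steps.
#' @param include_fd include the finite-N delay-atom drift term.
#' @param snapshots also record full weight profiles (memory permitting).
#' @param seed seed for the default random initial condition.
#' @return object of class `stdp_trajectory`: a list with tibble
#'   `order_params` (`time` in rescaled units, `w_bar`, `w_tilde`, `psi`),
#'   the final weights, optional `snapshots` matrix, and the `model`, `rule`
#'   and integration settings.
#' @export
#' @examples
#' m <- thalamic_model(n = 50)
#' r <- stdp_rule()
#' traj <- euler_integrate(m, r, n_steps = 2000, seed = 1)
#' glance(traj)
euler_integrate <- function(model, rule, init = NULL, n_steps = 1e5, dt = 0.1,
                            record_every = 10, include_fd = TRUE,
                            snapshots = FALSE, seed = NULL) {
  stopifnot(inherits(model, "thalamic_model"), inherits(rule, "stdp_rule"))
  if (dt <= 0) abort("`dt` must be positive.")
  if (is.null(init)) {
    draw <- function() runif(model$n, 0.3, 0.7)
    init <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  stopifnot(length(init) == model$n)
  check_weight_domain(init)
  kf <- kernel_fourier(rule, model$nu)
  res <- mf_euler_core(
    w0 = init, phases = model$phases,
    n_steps = as.integer(n_steps), ds = rule$lambda * dt,
    D = model$rate, gamma_mod = model$gamma, nu = model$nu,
    delay = model$delay, mu = rule$mu, alpha = rule$alpha,
    kt_plus = kf$k_tilde_plus, om_plus = kf$omega_plus,
    kt_minus = kf$k_tilde_minus, om_minus = kf$omega_minus,
    kp_d = kernel_value(rule, "+", model$delay),
    km_d = kernel_value(rule, "-", model$delay),
    include_fd = include_fd, record_every = as.integer(record_every),
    snapshots = snapshots)
  structure(
    list(order_params = tibble(time = res$time, w_bar = res$w_bar,
                               w_tilde = res$w_tilde, psi = res$psi),
         w_final = res$w_final,
         snapshots = res$snapshots,
         init = init,
         model = model, rule = rule,
         n_steps = n_steps, dt = dt, record_every = record_every,
         include_fd = include_fd,
         kind = "meanfield"),
    class = "stdp_trajectory")
}

#' @export
print.stdp_trajectory <- function(x, ...) {
  op <- x$order_params
  cat(sprintf("<STDP trajectory> (%s) %d recorded states over s = [%g, %g]\n",
              x$kind, nrow(op), op$time[1], op$time[nrow(op)]))
  cat(sprintf("  final: w_bar = %.4f, w_tilde = %.4f\n",
              op$w_bar[nrow(op)], op$w_tilde[nrow(op)]))
  invisible(x)
}

#' Write a trajectory's order parameters to CSV
#'
#' Columns: `time` (rescaled units), `w_bar`, `w_tilde`, `psi`.
#'
#' @param traj an `stdp_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "stdp_trajectory"))
  utils::write.csv(traj$order_params, path, row.names = FALSE)
  invisible(path)
}
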