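#' Named study presets
#'
#' Ready-made run configurations for the canonical parameter studies:
#' the quenched pooling baseline (`fig2`), the headline drifting-phase
#' simulation (`fig3`), the population-size study (`fig4`), and the sweeps
#' over upstream concentration (`fig5`), whisking frequency for both kernel
#' families (`fig6`, `fig7`), the weight-dependence exponent (`fig8`,
#' `fig9`), the relative depression strength (`fig10`) and the kernel time
#' constants (`fig11`). Units follow the conventional lab notation (Hz,
#' ms); they are converted to SI when a config is resolved.
#'
#' @return named list of config lists understood by [whisk_run()].
#' @export
#' @examples
#' names(whisk_presets())
#' whisk_presets()$fig3$model
whisk_presets <- function() {
  base_model <- list(n = 150, rate_hz = 10, gamma = 1, whisk_freq_hz = 7,
                     delay_ms = 3, kappa_vpm = 1, psi_vpm = 5 * pi / 6)
  base_rule <- list(family = "asymmetric_exponential", tau_plus_ms = 22,
                    tau_minus_ms = 50, mu = 0.01, alpha = 1.1, lambda = 0.01)
  run_mf <- list(mode = "meanfield", steps = 1e5, dt = 0.1, record_every = 10,
                 seed = 1, phase_mode = "quantile")
  list(
    fig2 = list(
      model = modifyList(base_model, list(psi_vpm = 0)),
      run = list(mode = "baseline", reps = 10000, seed = 1,
                 pool_sizes = c(1, 3, 10, 30, 100),
                 pool_modes = c("uniform", "random"),
                 kappa_values = c(1, 2))),
    fig3 = list(model = base_model, rule = base_rule, run = run_mf),
    fig4 = list(
      model = modifyList(base_model, list(gamma = 0.9)),
      rule = base_rule,
      run = modifyList(run_mf, list(phase_mode = "sample")),
      sweep = list(param = "n", grid = c(25, 50, 100, 150, 300))),
    fig5 = list(
      model = base_model, rule = base_rule, run = run_mf,
      sweep = list(param = "kappa_vpm", grid = c(0, 0.5, 1, 1.5, 2))),
    fig6 = list(
      model = modifyList(base_model, list(gamma = 0.9)),
      rule = base_rule, run = run_mf,
      sweep = list(param = "whisk_freq_hz", grid = c(3, 5, 7, 10, 14, 20, 40))),
    fig7 = list(
      model = modifyList(base_model, list(gamma = 0.9, delay_ms = 10)),
      rule = modifyList(base_rule, list(family = "symmetric_gaussian")),
      run = run_mf,
      sweep = list(param = "whisk_freq_hz", grid = c(3, 5, 7, 10, 14, 20, 40))),
    fig8 = list(
      model = modifyList(base_model, list(gamma = 0.9)),
      rule = base_rule, run = run_mf,
      sweep = list(param = "mu", grid = c(0.01, 0.06, 0.07, 0.1))),
    fig9 = list(
      model = modifyList(base_model, list(gamma = 0.9)),
      rule = base_rule, run = run_mf,
      sweep = list(param = "mu", grid = c(0.01, 0.03, 0.05, 0.07, 0.1))),
    fig10 = list(
      model = base_model, rule = base_rule, run = run_mf,
      sweep = list(param = "alpha", grid = c(0.9, 1, 1.05, 1.1, 1.2, 1.5))),
    fig11 = list(
      model = modifyList(base_model, list(delay_ms = 10)),
      rule = base_rule, run = run_mf,
      sweep = list(param = "tau_minus_ms", grid = c(30, 40, 50, 60, 80))))
}

#' @importFrom utils modifyList
NULL

# resolve a config list (paper units) into validated model + rule objects
resolve_config <- function(config) {
  m <- config$model
  if (is.null(m)) abort("config is missing the `model` block.")
  required <- c("n", "rate_hz", "gamma", "whisk_freq_hz", "delay_ms",
                "kappa_vpm", "psi_vpm")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(paste0("config$model is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  run <- config$run %||% list()
  model <- thalamic_model(
    n = m$n, rate = m$rate_hz, gamma = m$gamma,
    freq_hz = m$whisk_freq_hz, delay = m$delay_ms / 1000,
    input = von_mises_spec(m$kappa_vpm, m$psi_vpm),
    phase_mode = run$phase_mode %||% "quantile",
    seed = run$seed)
  rule <- NULL
  if (!is.null(config$rule)) {
    r <- config$rule
    rule <- stdp_rule(
      family = r$family %||% "asymmetric_exponential",
      tau_plus = (r$tau_plus_ms %||% 22) / 1000,
      tau_minus = (r$tau_minus_ms %||% 50) / 1000,
      mu = r$mu %||% 0.01, alpha = r$alpha %||% 1.1,
      lambda = r$lambda %||% 0.01)
  }
  list(model = model, rule = rule, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
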