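#' Preferred phase of a weighted pool
#'
#' A downstream neuron that linearly pools rhythmic inputs prefers the phase
#' of the summed rate: the argument of the weighted resultant
#' \eqn{\sum_k w_k e^{i\phi_k}}, shifted by the delay lag `nu * d`.
#'
#' @param phases upstream preferred phases, radians.
#' @param weights non-negative weights, same length, not all zero.
#' @param nu whisking angular frequency, rad/s.
#' @param delay transmission delay, seconds.
#' @return list with `phase` (wrapped; NA when the resultant vanishes) and
#'   `defined`.
#' @export
pooled_phase <- function(phases, weights = rep(1, length(phases)), nu = 0,
                         delay = 0) {
  stopifnot(length(phases) == length(weights))
  if (any(weights < 0) || all(weights == 0)) {
    abort("weights must be non-negative and not all zero.")
  }
  z <- sum(weights * exp(1i * phases))
  if (Mod(z) < 1e-12 * sum(weights)) {
    return(list(phase = NA_real_, defined = FALSE))
  }
  list(phase = wrap_angle(Arg(z) + nu * delay), defined = TRUE)
}

#' Quenched-disorder pooling ensemble
#'
#' The plasticity-free baseline: repeatedly draw `n` upstream phases i.i.d.
#' from the von Mises input distribution (and, in `"random"` mode, i.i.d.
#' uniform(0, 1) weights), pool them, and fit a von Mises to the resulting
#' downstream phases across repetitions. All variability is quenched -
#' frozen into which neurons were drawn - rather than temporal.
#'
#' @param spec upstream [von_mises_spec()].
#' @param n number of pooled neurons per repetition.
#' @param reps repetitions (>= 100 so the fit is meaningful).
#' @param mode `"uniform"` (equal weights) or `"random"` (i.i.d. uniform
#'   weights; the weight law is configurable via `weight_fn`).
#' @param nu,delay whisking angular frequency (rad/s) and delay (s) added as
#'   a constant lag.
#' @param seed integer seed.
#' @param weight_fn weight generator for `"random"` mode, a
#'   `function(n)`; default `runif`.
#' @return object of class `pooling_ensemble`: the downstream `phases`
#'   (length `reps`), the fitted `vm_spec`, and the settings.
#' @export
#' @examples
#' quenched_ensemble(von_mises_spec(1), n = 10, reps = 500, seed = 1)
quenched_ensemble <- function(spec, n, reps = 10000,
                              mode = c("uniform", "random"),
                              nu = 0, delay = 0, seed = NULL,
                              weight_fn = runif) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "vm_spec"))
  if (reps < 100) abort("need reps >= 100 for a meaningful fit.")
  run <- function() {
    draws <- matrix(sample_phases_accept_reject(spec, n * reps), nrow = reps)
    w <- if (mode == "random") {
      matrix(weight_fn(n * reps), nrow = reps)
    } else {
      matrix(1, nrow = reps, ncol = n)
    }
    z <- rowSums(w * exp(1i * draws))
    wrap_angle(Arg(z) + nu * delay)
  }
  phases <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(phases = phases, fit = fit_von_mises(phases),
         mode = mode, n = n, reps = reps, input = spec,
         nu = nu, delay = delay),
    class = "pooling_ensemble")
}

#' @export
print.pooling_ensemble <- function(x, ...) {
  cat(sprintf(
    "<pooling ensemble> %s pooling of N = %d, %d repetitions\n",
    x$mode, x$n, x$reps))
  cat(sprintf("  downstream fit: kappa = %.3f, psi = %.3f rad (input kappa = %g)\n",
              x$fit$kappa, x$fit$psi, x$input$kappa))
  invisible(x)
}

#' Write a pooling ensemble to disk
#'
#' @param x a `pooling_ensemble`.
#' @param json_path,csv_path summary JSON and per-repetition phase CSV
#'   (`NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_ensemble <- function(x, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(x, "pooling_ensemble"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(mode = x$mode, n = x$n, reps = x$reps,
           kappa_l4i = x$fit$kappa, psi_l4i = x$fit$psi,
           input_kappa = x$input$kappa, input_psi = x$input$psi),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(phase_rad = x$phases), csv_path,
                     row.names = FALSE)
  }
  invisible(x)
}
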