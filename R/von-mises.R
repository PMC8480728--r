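#' Von Mises specification
#'
#' The circular-normal distribution used throughout: for the preferred phases
#' of the upstream (thalamic) population and for fitted phase distributions of
#' the downstream neuron. Density
#' \deqn{\Pr(\phi) = \frac{e^{\kappa\cos(\phi - \psi)}}{2\pi I_0(\kappa)},}
#' where `kappa >= 0` is the concentration (0 = uniform) and `psi` the mean
#' direction.
#'
#' @param kappa non-negative concentration.
#' @param psi mean direction, radians; wrapped to `[-pi, pi)`.
#' @return an object of class `vm_spec` with fields `kappa`, `psi`.
#' @export
#' @examples
#' von_mises_spec(1, 5 * pi / 6)
von_mises_spec <- function(kappa, psi = 0) {
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) || kappa < 0) {
    abort("`kappa` must be a single non-negative number.",
          class = "whiskstdp_invalid_parameter")
  }
  structure(list(kappa = as.numeric(kappa), psi = wrap_angle(as.numeric(psi))),
            class = "vm_spec")
}

#' @export
print.vm_spec <- function(x, ...) {
  cat(sprintf("<von Mises spec> kappa = %g, psi = %g rad\n", x$kappa, x$psi))
  invisible(x)
}

#' Von Mises density
#'
#' @param spec a [von_mises_spec()].
#' @param phi numeric vector of angles, radians (any real; density is
#'   2*pi-periodic).
#' @return non-negative density values.
#' @export
von_mises_density <- function(spec, phi) {
  stopifnot(inherits(spec, "vm_spec"))
  # exponentially scaled Bessel keeps this stable at large kappa
  exp(spec$kappa * (cos(phi - spec$psi) - 1)) /
    (2 * pi * besselI(spec$kappa, 0, expon.scaled = TRUE))
}

# cumulative distribution from -pi, via adaptive quadrature
vm_cdf <- function(spec, phi) {
  vapply(phi, function(p) {
    if (p <= -pi) return(0)
    integrate(function(x) von_mises_density(spec, x), -pi, min(p, pi),
              rel.tol = 1e-12, abs.tol = 1e-13)$value
  }, numeric(1))
}

#' Deterministic quantile placement of preferred phases
#'
#' Places `n` phases so that the k-th satisfies
#' \eqn{\int_{-\pi}^{\phi_k} \Pr(\phi)\,d\phi = k/n}: the noiseless
#' ("no quenched disorder") representation of the upstream phase
#' distribution. The CDF is inverted by bisection to an absolute tolerance
#' of 1e-10.
#'
#' @inheritParams von_mises_density
#' @param n number of phases (positive integer).
#' @return sorted numeric vector of `n` phases in `[-pi, pi)`.
#' @export
#' @examples
#' place_phases_quantile(von_mises_spec(0), 4)
place_phases_quantile <- function(spec, n) {
  stopifnot(inherits(spec, "vm_spec"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.", class = "whiskstdp_invalid_parameter")
  }
  n <- as.integer(n)
  targets <- seq_len(n) / n
  phases <- vapply(targets, function(q) {
    if (q >= 1) return(pi)
    lo <- -pi; hi <- pi
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (vm_cdf(spec, mid) < q) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  sort(wrap_angle(phases))
}

#' Accept-reject sampling of preferred phases
#'
#' I.i.d. draws from the von Mises density using a uniform proposal on
#' `[-pi, pi)` with envelope constant \eqn{e^\kappa / (2\pi I_0(\kappa))};
#' the acceptance probability of a proposal \eqn{\phi} is
#' \eqn{e^{\kappa(\cos(\phi-\psi)-1)}}.
#'
#' @inheritParams place_phases_quantile
#' @param seed integer seed; the draw is reproducible given the seed. `NULL`
#'   uses (and advances) the current RNG state.
#' @return numeric vector of `n` phases in `[-pi, pi)` (unsorted).
#' @export
sample_phases_accept_reject <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "vm_spec"))
  n <- as.integer(n)
  stopifnot(n >= 1)
  # mean acceptance probability under the uniform proposal is I0(k) e^-k
  acc_rate <- besselI(spec$kappa, 0, expon.scaled = TRUE)
  draw <- function() {
    out <- numeric(0)
    while (length(out) < n) {
      m <- 64L + ceiling((n - length(out)) / acc_rate * 1.2)
      prop <- runif(m, -pi, pi)
      keep <- runif(m) < exp(spec$kappa * (cos(prop - spec$psi) - 1))
      out <- c(out, prop[keep])
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Maximum-likelihood (or histogram least-squares) von Mises fit
#'
#' Default is the maximum-likelihood estimator on (optionally weighted)
#' angular samples: the mean direction is the argument of the resultant
#' vector and the concentration solves
#' \eqn{\bar R = I_1(\kappa)/I_0(\kappa)} by bisection (tolerance 1e-8).
#' `method = "nls"` instead bins the samples and fits the von Mises density
#' to the histogram by nonlinear least squares, the procedure classically
#' used for tuning-curve style fits; both agree closely on well-sampled
#' unimodal data.
#'
#' @param theta numeric vector of angles, radians.
#' @param weights optional non-negative weights (e.g. time steps for a
#'   temporally sampled trajectory); default equal weights.
#' @param method `"ml"` (default) or `"nls"`.
#' @param n_bins histogram bins for `method = "nls"` (default 36).
#' @return a [von_mises_spec()] with attributes `R_bar` (mean resultant
#'   length) and `n` (effective sample count).
#' @export
#' @examples
#' th <- sample_phases_accept_reject(von_mises_spec(2, 1), 2000, seed = 1)
#' fit_von_mises(th)
fit_von_mises <- function(theta, weights = NULL, method = c("ml", "nls"),
                          n_bins = 36) {
  method <- match.arg(method)
  if (length(theta) == 0) abort("cannot fit a von Mises to zero samples.")
  if (is.null(weights)) weights <- rep(1, length(theta))
  stopifnot(length(weights) == length(theta), all(weights >= 0), sum(weights) > 0)
  z <- sum(weights * exp(1i * theta)) / sum(weights)
  r_bar <- Mod(z)
  psi_hat <- if (r_bar > 1e-12) Arg(z) else 0
  kappa_hat <- invert_resultant(r_bar)
  if (method == "nls") {
    h <- weighted_phase_histogram(theta, weights, n_bins)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        density ~ exp(k * (cos(mid - p) - 1)) /
          (2 * pi * besselI(k, 0, expon.scaled = TRUE)),
        data = h,
        start = list(k = max(kappa_hat, 1e-3), p = psi_hat),
        lower = c(k = 0, p = -2 * pi), upper = c(k = 500, p = 2 * pi),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      kappa_hat <- unname(co["k"])
      psi_hat <- unname(co["p"])
    }
  }
  out <- von_mises_spec(kappa_hat, wrap_angle(psi_hat))
  attr(out, "R_bar") <- r_bar
  attr(out, "n") <- length(theta)
  out
}

# solve I1(k)/I0(k) = r by bisection; r in [0, 1)
invert_resultant <- function(r) {
  if (r <= 1e-12) return(0)
  if (r >= 1 - 1e-12) return(1e8)
  a_ratio <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  hi <- 1
  while (a_ratio(hi) < r && hi < 1e8) hi <- hi * 2
  lo <- 0
  while (hi - lo > 1e-8 * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (a_ratio(mid) < r) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

weighted_phase_histogram <- function(theta, weights, n_bins) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  theta <- wrap_angle(theta)
  idx <- pmin(findInterval(theta, edges, rightmost.closed = TRUE), n_bins)
  mass <- vapply(seq_len(n_bins), function(b) sum(weights[idx == b]), numeric(1))
  width <- 2 * pi / n_bins
  tibble(
    mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    density = mass / (sum(weights) * width)
  )
}
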