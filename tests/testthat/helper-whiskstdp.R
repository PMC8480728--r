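# shared fixtures, built in code

fig3_model <- function(n = 150) {
  thalamic_model(n = n, rate = 10, gamma = 1, freq_hz = 7, delay = 0.003,
                 input = von_mises_spec(1, 5 * pi / 6))
}

fig3_rule <- function(mu = 0.01, alpha = 1.1, lambda = 0.01) {
  stdp_rule("asymmetric_exponential", tau_plus = 0.022, tau_minus = 0.050,
            mu = mu, alpha = alpha, lambda = lambda)
}

# the headline drifting-phase trajectory, computed once per test run
fig3_trajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- euler_integrate(fig3_model(), fig3_rule(),
                                n_steps = 1e5, dt = 0.1,
                                record_every = 10, seed = 42)
    }
    cache
  }
})

# independent series oracle for the modified Bessel function I_nu(x)
bessel_i_series <- function(x, nu = 0, terms = 60) {
  m <- 0:terms
  sum((x / 2)^(2 * m + nu) / (factorial(m) * gamma(m + nu + 1)))
}

expect_wrapped <- function(x) {
  expect_true(all(x >= -pi & x < pi))
}
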