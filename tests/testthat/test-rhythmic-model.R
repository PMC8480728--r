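test_that("von Mises density: uniform limit, peak value, normalization", {
  expect_equal(von_mises_density(von_mises_spec(0), 1.234), 1 / (2 * pi))
  expect_equal(von_mises_density(von_mises_spec(0), -2.5), 1 / (2 * pi))

  # peak at the mean direction against an independent series oracle for I0
  spec <- von_mises_spec(1, 0.4)
  expect_equal(von_mises_density(spec, 0.4),
               exp(1) / (2 * pi * bessel_i_series(1)), tolerance = 1e-10)

  # periodic and normalized for a range of concentrations
  for (k in c(0, 0.5, 1, 2, 5)) {
    s <- von_mises_spec(k, -1)
    expect_equal(von_mises_density(s, 0.3), von_mises_density(s, 0.3 + 2 * pi))
    total <- integrate(function(x) von_mises_density(s, x), -pi, pi,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(von_mises_spec(-0.1), class = "whiskstdp_invalid_parameter")
})

test_that("thalamic rate follows the whisking cycle", {
  m <- thalamic_model(n = 3, rate = 10, gamma = 0, freq_hz = 7,
                      phases = c(-1, 0, 1))
  expect_equal(thalamic_rate(m, 2, 0.123), 10)

  m1 <- thalamic_model(n = 3, rate = 10, gamma = 1, freq_hz = 1,
                       phases = c(-1, 0, 1))
  t_peak <- m1$phases[3] / m1$nu
  expect_equal(thalamic_rate(m1, 3, t_peak), 20)   # peak D(1 + gamma)

  m2 <- thalamic_model(n = 3, rate = 10, gamma = 0.5, freq_hz = 1,
                       phases = c(-1, 0, 1))
  t_trough <- (m2$phases[2] + pi) / m2$nu
  expect_equal(thalamic_rate(m2, 2, t_trough), 5)  # trough D(1 - gamma)

  expect_error(thalamic_rate(m, 4, 0))
  expect_error(thalamic_model(gamma = 1.2), class = "whiskstdp_invalid_parameter")
})

test_that("quantile placement inverts the CDF", {
  # uniform distribution: quantiles at multiples of pi/2, k/N convention
  ph <- place_phases_quantile(von_mises_spec(0), 4)
  expect_equal(ph, c(-pi, -pi / 2, 0, pi / 2), tolerance = 1e-9)

  # strong concentration pulls the interior phases onto the mean; the last
  # phase is pinned at the 100th percentile (pi) by the k/N convention
  ph50 <- place_phases_quantile(von_mises_spec(50, 1), 4)
  interior <- ph50[abs(circ_diff(ph50, pi)) > 1e-6]
  expect_equal(length(interior), 3)
  expect_true(all(abs(circ_diff(interior, 1)) < 0.5))

  # against a brute-force CDF inversion on a dense grid
  spec <- von_mises_spec(1, 0)
  grid <- seq(-pi, pi, length.out = 1e6 + 1)
  dens <- von_mises_density(spec, grid)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  expected <- sort(wrap_angle(approx(cdf, grid, xout = (1:10) / 10)$y))
  expect_equal(place_phases_quantile(spec, 10), expected, tolerance = 1e-5)
})

test_that("quantile-placed phases recover the generating distribution", {
  spec <- von_mises_spec(1.5, 0.7)
  ph <- place_phases_quantile(spec, 1e4)
  fit <- fit_von_mises(ph)
  expect_equal(fit$kappa, 1.5, tolerance = 0.05)
  expect_equal(fit$psi, 0.7, tolerance = 0.05)
})

test_that("accept-reject sampling is reproducible and recovers parameters", {
  spec <- von_mises_spec(1, 0.5)
  a <- sample_phases_accept_reject(spec, 1000, seed = 7)
  b <- sample_phases_accept_reject(spec, 1000, seed = 7)
  expect_identical(a, b)
  expect_wrapped(a)

  big <- sample_phases_accept_reject(spec, 1e5, seed = 1)
  fit <- fit_von_mises(big)
  expect_equal(fit$kappa, 1, tolerance = 0.05)
  expect_equal(fit$psi, 0.5, tolerance = 0.05)
})

test_that("order parameters: symmetry, cosine profile, singleton", {
  # constant weights on uniform phases: no first Fourier component
  ph <- place_phases_quantile(von_mises_spec(0), 100)
  op <- order_parameters(rep(0.4, 100), ph)
  expect_equal(op$w_bar, 0.4)
  expect_lt(op$w_tilde, 1e-12)
  expect_false(op$psi_defined)

  # w(phi) = a (1 + cos(phi - phi0)) has mean a and first component a/2;
  # oracle values from the defining integrals
  a <- 0.3; phi0 <- 1.1
  ph <- place_phases_quantile(von_mises_spec(0), 1e4)
  op <- order_parameters(a * (1 + cos(ph - phi0)), ph)
  expect_equal(op$w_bar, a, tolerance = 1e-3)
  expect_equal(op$w_tilde, a / 2, tolerance = 1e-3)
  expect_equal(op$psi, phi0, tolerance = 1e-3)

  op1 <- order_parameters(0.7, 1.2)
  expect_equal(op1$w_bar, 0.7)
  expect_equal(op1$w_tilde, 0.7)
  expect_equal(op1$psi, 1.2)

  expect_error(order_parameters(numeric(0), numeric(0)))
})

test_that("order parameters satisfy 0 <= w_tilde <= w_bar", {
  withr::with_seed(3, {
    for (i in 1:25) {
      n <- sample(2:200, 1)
      w <- runif(n)
      ph <- runif(n, -pi, pi)
      op <- order_parameters(w, ph)
      expect_gte(op$w_tilde, 0)
      expect_lte(op$w_tilde, op$w_bar + 1e-12)
    }
  })
})

test_that("downstream tuning and its scaling invariance", {
  m <- fig3_model(n = 100)
  w <- 0.2 + 0.5 * (1 + cos(m$phases - 0.3)) / 2
  op <- order_parameters(w, m$phases)
  tun <- downstream_tuning(op, m)
  expect_equal(tun$d_l4i, m$rate * op$w_bar)
  expect_equal(tun$gamma_l4i, m$gamma * op$w_tilde / op$w_bar)
  expect_equal(tun$psi_l4i, wrap_angle(op$psi + m$nu * m$delay))

  # global weight scaling: rate scales, tuning shape unchanged
  op2 <- order_parameters(0.5 * w, m$phases)
  tun2 <- downstream_tuning(op2, m)
  expect_equal(tun2$d_l4i, 0.5 * tun$d_l4i)
  expect_equal(tun2$gamma_l4i, tun$gamma_l4i)
  expect_equal(tun2$psi_l4i, tun$psi_l4i)

  # no first component -> no preferred phase, zero modulation
  flat <- order_parameters(rep(0.5, 100),
                           place_phases_quantile(von_mises_spec(0), 100))
  tf <- downstream_tuning(flat, m)
  expect_equal(tf$gamma_l4i, 0)
  expect_true(is.na(tf$psi_l4i))
})

test_that("angle wrapping is canonical and idempotent", {
  x <- c(0, pi, -pi, 3 * pi, -3 * pi, 7.5, -7.5)
  w <- wrap_angle(x)
  expect_wrapped(w)
  expect_equal(wrap_angle(w), w)
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
  expect_equal(cos(w), cos(x), tolerance = 1e-12)
})
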