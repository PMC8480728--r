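make_traj <- function(psi, times = seq_along(psi) - 1, w_tilde = 0.2,
                      model = fig3_model(n = 10)) {
  structure(
    list(order_params = tibble::tibble(
      time = times, w_bar = 0.5, w_tilde = w_tilde,
      psi = wrap_angle(psi)),
      model = model, rule = fig3_rule(), kind = "synthetic"),
    class = "stdp_trajectory")
}

test_that("phase trajectory applies the delay shift and flags invalid samples", {
  m <- fig3_model(n = 10)
  tr <- make_traj(rep(0.7, 20), model = m)
  pt <- phase_trajectory(tr)
  expect_equal(pt$psi_l4i, rep(wrap_angle(0.7 + m$nu * m$delay), 20))

  m0 <- thalamic_model(n = 10, rate = 10, gamma = 1, freq_hz = 7, delay = 0)
  pt0 <- phase_trajectory(make_traj(rep(0.7, 20), model = m0))
  expect_equal(pt0$psi_l4i, rep(0.7, 20))

  tr2 <- make_traj(c(rep(0.7, 10), rep(0.7, 10)),
                   w_tilde = c(rep(0.2, 10), rep(0, 10)))
  expect_equal(sum(phase_trajectory(tr2)$valid), 10)
})

test_that("unwrapping and drift velocity on known series", {
  t <- seq(0, 10, by = 0.05)
  lin <- unwrap_and_velocity(wrap_angle(0.8 * t), t)
  expect_equal(lin$velocity, rep(0.8, length(t)), tolerance = 1e-9)
  expect_equal(diff(range(diff(lin$phase_unwrapped))), 0, tolerance = 1e-9)

  still <- unwrap_and_velocity(rep(1.1, 50), seq_len(50))
  expect_equal(still$velocity, rep(0, 50))

  expect_error(unwrap_and_velocity(wrap_angle(2 * seq(0, 20)), seq(0, 20)),
               class = "whiskstdp_undersampled")
})

test_that("constant-velocity drift yields a uniform phase distribution", {
  t <- seq(0, 100, by = 0.02)
  tr <- make_traj(0.9 * t, times = t,
                  model = thalamic_model(n = 10, rate = 10, gamma = 1,
                                         freq_hz = 7, delay = 0))
  d <- temporal_phase_distribution(tr, transient_fraction = 0.2)
  expect_lt(d$fit$kappa, 0.02)
  expect_gte(d$n_cycles, 3)
  # histogram is a proper density
  expect_equal(sum(d$histogram$density) * 2 * pi / d$n_bins, 1,
               tolerance = 1e-9)
})

test_that("too few drift cycles is an error, not a silent fit", {
  t <- seq(0, 10, by = 0.02)
  tr <- make_traj(0.9 * t, times = t)  # < 2 full turns after transient
  expect_error(temporal_phase_distribution(tr),
               class = "whiskstdp_too_few_cycles")
})

test_that("von Mises fitting: recovery, boundary, rotation equivariance", {
  u <- runif_seeded <- withr::with_seed(21, runif(1e5, -pi, pi))
  expect_lt(fit_von_mises(u)$kappa, 0.02)

  s <- sample_phases_accept_reject(von_mises_spec(2, 1), 1e5, seed = 22)
  f <- fit_von_mises(s)
  expect_equal(f$kappa, 2, tolerance = 0.05 / 2)
  expect_equal(f$psi, 1, tolerance = 0.02)

  # rotating the samples rotates the fitted mean, not the concentration
  rot <- fit_von_mises(wrap_angle(s + 0.6))
  expect_equal(rot$kappa, f$kappa, tolerance = 1e-10)
  expect_lt(abs(circ_diff(rot$psi, f$psi + 0.6)), 1e-10)

  # degenerate resultant
  expect_equal(fit_von_mises(c(0, pi))$kappa, 0)
})

test_that("histogram least-squares mode agrees with maximum likelihood", {
  for (k in c(0.5, 1.5, 3)) {
    s <- sample_phases_accept_reject(von_mises_spec(k, -0.4), 2e4,
                                     seed = 30 + k * 10)
    ml <- fit_von_mises(s, method = "ml")
    nls <- fit_von_mises(s, method = "nls")
    expect_equal(nls$kappa, ml$kappa, tolerance = 0.1 * ml$kappa)
    expect_lt(abs(circ_diff(nls$psi, ml$psi)), 0.1)
  }
})

test_that("modulation depth series and the uniform-pooling benchmark", {
  # uniform weights: no modulation at all
  m <- fig3_model(n = 50)
  tr <- make_traj(rep(0.2, 30), w_tilde = 0, model = m)
  tr$order_params$w_tilde <- 0
  ms <- modulation_series(tr)
  expect_equal(ms$gamma_l4i, rep(0, 30))

  # pooling the whole population uniformly transmits gamma * I1(k)/I0(k)
  spec <- von_mises_spec(1.3, 0.2)
  ph <- place_phases_quantile(spec, 1e4)
  op <- order_parameters(rep(1, 1e4), ph)
  tun <- downstream_tuning(op, m)
  bench <- m$gamma * bessel_i_series(1.3, 1) / bessel_i_series(1.3, 0)
  expect_equal(tun$gamma_l4i, bench, tolerance = 1e-3)

  # cosine profile on uniform inputs halves the modulation depth
  phu <- place_phases_quantile(von_mises_spec(0), 1e4)
  opc <- order_parameters((1 + cos(phu - 0.5)) / 2, phu)
  tunc <- downstream_tuning(opc, m)
  expect_equal(tunc$gamma_l4i, m$gamma / 2, tolerance = 1e-3)
})

test_that("fig-3 drift has phase-dependent speed of a single sign", {
  traj <- fig3_trajectory()
  pt <- phase_trajectory(traj)
  keep <- pt$valid
  half <- floor(sum(keep) / 2)
  seg <- pt[keep, ][half:sum(keep), ]
  uv <- unwrap_and_velocity(seg$psi_l4i, seg$time)
  v <- uv$velocity[10:(nrow(uv) - 10)]
  expect_true(all(v < 0) || all(v > 0))   # monotone drift
  expect_gt(diff(range(abs(v))) / mean(abs(v)), 0.5)  # far from constant
})

test_that("occupancy matches inverse drift speed along the limit cycle", {
  ov <- occupancy_vs_velocity(fig3_trajectory())
  expect_gt(cor(ov$density, ov$inv_speed_density), 0.95)
})

test_that("time weighting uses the actual sampling intervals", {
  # irregular sampling of a constant-speed drift must still be uniform
  withr::with_seed(44, {
    t <- sort(c(seq(0, 100, by = 0.02), runif(2000, 0, 100)))
  })
  tr <- make_traj(0.9 * t, times = t,
                  model = thalamic_model(n = 10, rate = 10, gamma = 1,
                                         freq_hz = 7, delay = 0))
  d <- temporal_phase_distribution(tr, transient_fraction = 0.2)
  expect_lt(d$fit$kappa, 0.05)
})
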