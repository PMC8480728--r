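test_that("pre-pre cross-correlation: smooth part and Poisson atom", {
  m <- thalamic_model(n = 4, rate = 10, gamma = 0, freq_hz = 7,
                      phases = c(-2, -1, 0.5, 2))
  cc <- cross_corr_pre_pre(m, 1, 2, 0.013)
  expect_equal(cc$smooth, 100)      # gamma = 0: rates uncorrelated in phase
  expect_equal(cc$delta_weight, 0)

  m1 <- thalamic_model(n = 4, rate = 10, gamma = 1, freq_hz = 7,
                       phases = c(0.5, 0.5, 1, 2))
  # equal phases at zero lag: D^2 (1 + gamma^2/2)
  expect_equal(cross_corr_pre_pre(m1, 1, 2, 0)$smooth, 150)
  expect_equal(cross_corr_pre_pre(m1, 3, 3, 0.2)$delta_weight, 10)
})

test_that("pre-post cross-correlation is the weighted pre-pre average", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(3:8, 1)
      m <- thalamic_model(n = n, rate = 8, gamma = runif(1), freq_hz = 5,
                          delay = 0.004, phases = runif(n, -pi, pi))
      w <- runif(n)
      op <- order_parameters(w, m$phases)
      for (dt in c(-0.07, 0, 0.013)) {
        j <- sample(n, 1)
        # brute-force summation over the upstream population
        brute <- mean(vapply(seq_len(n), function(k) {
          w[k] * cross_corr_pre_pre(m, j, k, dt - m$delay)$smooth
        }, numeric(1)))
        got <- cross_corr_pre_post(j, w, op, m, dt)
        expect_equal(got$smooth, brute, tolerance = 1e-10)
        expect_equal(got$delta_weight_at_d, w[j] * m$rate / n)
        expect_equal(got$delta_time, m$delay)
      }
    }
  })
  # uniform weights on a uniform phase distribution carry no rhythmic part
  m <- thalamic_model(n = 20, rate = 10, gamma = 1, freq_hz = 7,
                      delay = 0.003, input = von_mises_spec(0))
  w <- rep(0.5, 20)
  op <- order_parameters(w, m$phases)
  s1 <- cross_corr_pre_post(1, w, op, m, 0.01)$smooth
  s2 <- cross_corr_pre_post(1, w, op, m, 0.05)$smooth
  expect_equal(s1, m$rate^2 * 0.5, tolerance = 1e-9)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("drift terms: balance point and causal delay atom", {
  m <- fig3_model(n = 40)
  rule <- fig3_rule(mu = 0.2)
  w_star <- (1 + rule$alpha^(1 / rule$mu))^-1
  w <- rep(w_star, 40)
  op <- order_parameters(w, m$phases)
  dt <- drift_terms(w, m$phases, op, rule, m)
  expect_equal(dt$f_0, rep(0, 40), tolerance = 1e-12)

  # asymmetric kernel: depression branch vanishes at positive delay
  w2 <- runif(40, 0.2, 0.8)
  op2 <- order_parameters(w2, m$phases)
  dt2 <- drift_terms(w2, m$phases, op2, rule, m)
  expect_true(all(dt2$f_d >= 0))
  expect_equal(dt2$f_d,
               w2 * (m$rate / m$n) * f_plus(w2, rule$mu) *
                 exp(-m$delay / rule$tau_plus) / rule$tau_plus,
               tolerance = 1e-12)
})

test_that("mean-field RHS agrees with direct quadrature of the learning integrals", {
  # oracle: dw_j/ds = f+(w_j) int Gamma_j,post(D) K+(D) dD - (f- term),
  # the smooth correlation integrated adaptively plus the delta atom at d
  withr::with_seed(5, {
    for (fam in c("asymmetric_exponential", "symmetric_gaussian")) {
      n <- 8
      m <- thalamic_model(n = n, rate = 10, gamma = 0.9, freq_hz = 7,
                          delay = 0.003, phases = sort(runif(n, -pi, pi)))
      rule <- stdp_rule(fam, 0.022, 0.050, mu = 0.05, alpha = 1.1)
      w <- runif(n, 0.1, 0.9)
      op <- order_parameters(w, m$phases)
      oracle <- vapply(seq_len(n), function(j) {
        term <- function(br) {
          tau <- if (br == "+") rule$tau_plus else rule$tau_minus
          smooth <- integrate(function(x) {
            cross_corr_pre_post(j, w, op, m, x)$smooth *
              kernel_value(rule, br, x)
          }, -36 * tau, 36 * tau, rel.tol = 1e-12,
          subdivisions = 4000)$value
          atom <- w[j] * m$rate / n * kernel_value(rule, br, m$delay)
          smooth + atom
        }
        f_plus(w[j], rule$mu) * term("+") -
          f_minus(w[j], rule$mu, rule$alpha) * term("-")
      }, numeric(1))
      got <- meanfield_rhs(w, m$phases, rule, m)
      expect_equal(got, oracle, tolerance = 1e-6)
    }
  })
})

test_that("RHS symmetry and homogeneity in the rate", {
  # uniform input distribution + uniform weights: identical velocity everywhere
  m <- thalamic_model(n = 30, rate = 10, gamma = 1, freq_hz = 7,
                      delay = 0.003, input = von_mises_spec(0))
  w <- rep(0.4, 30)
  rhs <- meanfield_rhs(w, m$phases, fig3_rule(), m)
  expect_lt(diff(range(rhs)), 1e-10)

  # without the finite-N term the RHS is quadratic in D
  m2 <- fig3_model(n = 30)
  m3 <- thalamic_model(n = 30, rate = 30, gamma = 1, freq_hz = 7,
                       delay = 0.003, input = von_mises_spec(1, 5 * pi / 6))
  w <- runif(30, 0.2, 0.8)
  r1 <- meanfield_rhs(w, m2$phases, fig3_rule(), m2, include_fd = FALSE)
  r3 <- meanfield_rhs(w, m3$phases, fig3_rule(), m3, include_fd = FALSE)
  expect_equal(r3, 9 * r1, tolerance = 1e-10)
})

test_that("Euler integration: saturation when potentiation dominates", {
  # alpha < 1 at high frequency: every synapse is driven to its ceiling
  m <- thalamic_model(n = 30, rate = 10, gamma = 0.9, freq_hz = 100,
                      delay = 0.003, input = von_mises_spec(1, 0))
  rule <- fig3_rule(alpha = 0.9)
  traj <- euler_integrate(m, rule, n_steps = 3e4, dt = 0.1, seed = 2)
  expect_true(all(traj$w_final > 0.9))
  expect_gt(mean(traj$w_final), 0.95)
})

test_that("Euler integration: high-frequency uniform solution, symmetric rule", {
  m <- thalamic_model(n = 50, rate = 10, gamma = 1, freq_hz = 200,
                      delay = 0.003, input = von_mises_spec(1, 5 * pi / 6))
  rule <- stdp_rule("symmetric_gaussian", 0.022, 0.050, mu = 0.1, alpha = 1.1)
  traj <- euler_integrate(m, rule, n_steps = 5e4, dt = 0.1,
                          include_fd = FALSE, seed = 3)
  w_star <- (1 + rule$alpha^(1 / rule$mu))^-1
  expect_true(all(abs(traj$w_final - w_star) < 1e-3))
})

test_that("trajectory weights stay in [0, 1] and step size is resolved", {
  traj <- fig3_trajectory()
  op <- traj$order_params
  expect_true(all(op$w_bar >= 0 & op$w_bar <= 1))
  expect_true(all(op$w_tilde <= op$w_bar + 1e-12))
  expect_true(all(traj$w_final >= 0 & traj$w_final <= 1))

  # halving the step and doubling the count: cycle-averaged order
  # parameters are unchanged (the endpoint phase along the cycle is the
  # only step-sensitive quantity)
  m <- fig3_model(n = 150)
  a <- euler_integrate(m, fig3_rule(), n_steps = 4e4, dt = 0.05, seed = 9)
  b <- euler_integrate(m, fig3_rule(), n_steps = 8e4, dt = 0.025, seed = 9)
  ca <- cycle_averages(a); cb <- cycle_averages(b)
  expect_gte(ca$n_cycles, 3)
  expect_lt(abs(ca$w_bar - cb$w_bar), 1e-3)
  expect_lt(abs(ca$w_tilde - cb$w_tilde), 1e-3)
  # and on a fixed-point regime the endpoint itself is step-robust
  mf <- thalamic_model(n = 40, rate = 10, gamma = 0.9, freq_hz = 7,
                       delay = 0.003, input = von_mises_spec(1, 5 * pi / 6))
  af <- euler_integrate(mf, fig3_rule(mu = 0.1), n_steps = 2e4, dt = 0.1,
                        seed = 9)
  bf <- euler_integrate(mf, fig3_rule(mu = 0.1), n_steps = 4e4, dt = 0.05,
                        seed = 9)
  expect_equal(af$w_final, bf$w_final, tolerance = 1e-3)
})

test_that("time-rescaling invariance of the integrator", {
  m <- fig3_model(n = 40)
  r1 <- fig3_rule(lambda = 0.01)
  r2 <- fig3_rule(lambda = 0.001)
  a <- euler_integrate(m, r1, n_steps = 5000, dt = 0.1, seed = 4)
  b <- euler_integrate(m, r2, n_steps = 5000, dt = 1.0, seed = 4)
  expect_identical(a$order_params$w_bar, b$order_params$w_bar)
  expect_identical(a$order_params$psi, b$order_params$psi)
})

test_that("limit cycle at small mu; fixed point at mu = 0.1", {
  # small mu: order parameters recur while the phase advances by full turns
  traj <- fig3_trajectory()
  op <- traj$order_params
  half <- op[op$time >= max(op$time) / 2, ]
  u <- unwrap_angle(half$psi)
  n_turns <- abs(u[length(u)] - u[1]) / (2 * pi)
  expect_gt(n_turns, 3)
  ref <- c(half$w_bar[1], half$w_tilde[1])
  rec <- min(sqrt((half$w_bar[-1] - ref[1])^2 + (half$w_tilde[-1] - ref[2])^2))
  expect_lt(rec, 1e-3)

  # mu = 0.1 (with gamma = 0.9): converges to a stationary profile
  m <- thalamic_model(n = 150, rate = 10, gamma = 0.9, freq_hz = 7,
                      delay = 0.003, input = von_mises_spec(1, 5 * pi / 6))
  tr <- euler_integrate(m, fig3_rule(mu = 0.1), n_steps = 6e4, dt = 0.1,
                        seed = 8)
  rhs <- meanfield_rhs(tr$w_final, m$phases, fig3_rule(mu = 0.1), m)
  expect_lt(max(abs(rhs)), 1e-6)
})
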