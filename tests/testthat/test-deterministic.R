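test_that("allele velocity vanishes at boundaries and symmetric equilibria", {
  arch <- trait_architecture(3, effects = c(0.01, 0.02, 0.03), mu = 0, nu = 0)
  reg <- selection_regime(0.1, 0.2)
  expect_equal(allele_velocity(c(0, 1, 0), arch, reg, delta_c1 = -0.5),
               rep(0, 3))
  arch_mu <- trait_architecture(3, effects = c(0.01, 0.02, 0.03), mu = 1e-5)
  expect_equal(allele_velocity(rep(0.5, 3), arch_mu, reg, delta_c1 = 0),
               rep(0, 3))
})

test_that("allele velocity matches term-by-term arithmetic", {
  g <- 0.01; p <- 0.3; s <- 0.1; mu <- 1e-5; d <- -0.3
  arch <- trait_architecture(1, effects = g, mu = mu)
  reg <- selection_regime(s, 0.2)
  q <- 1 - p
  want <- -s * g * p * q * d - (s * g^2 / 2) * p * q * (q - p) - mu * p + mu * q
  expect_equal(allele_velocity(p, arch, reg, d), want, tolerance = 1e-15)
  # matrix input: independent columns with their own mean deviations
  m <- cbind(rep(p, 1), rep(0.6, 1))
  v <- allele_velocity(matrix(c(p, 0.6), 1), arch, reg, c(d, 0.1))
  expect_equal(v[1, 1], want, tolerance = 1e-15)
})

test_that("deterministic integration preserves fixed points and length 0", {
  arch <- trait_architecture(4, effects = rep(0.01, 4), mu = 1e-5)
  reg <- selection_regime(0.1, 0.2)
  t0 <- integrate_deterministic(c(0.1, 0.4, 0.6, 0.9), arch, reg, 0)
  expect_equal(nrow(t0$cumulants), 1L)
  expect_equal(t0$final$freqs, c(0.1, 0.4, 0.6, 0.9))

  # p = 0.5 everywhere with the optimum at the (symmetric) mean is a fixed
  # point of the full dynamics: velocity is exactly 0 there
  regs <- selection_regime(0.1, 0, 0)
  p_star <- rep(0.5, 4)
  expect_true(all(abs(allele_velocity(p_star, arch, regs, 0)) < 1e-12))
  traj <- suppressWarnings(
    integrate_deterministic(p_star, arch, regs, 1000))
  expect_true(all(abs(traj$final$freqs - 0.5) < 1e-9))
})

test_that("deterministic mean trajectory follows the exponential law", {
  # small-effects architecture: many loci, intermediate frequencies
  arch <- trait_architecture(400, effects = rep(0.005, 400), mu = 1e-5)
  reg <- selection_regime(s = 0.1, z_initial = 0.001, z_final = 0.3)
  p0 <- rep(0.5, 400)
  c2_0 <- compute_cumulants(p0, arch)$c2
  horizon <- round(short_term_duration(reg$s, c2_0))
  traj <- integrate_deterministic(p0, arch, reg, horizon)$cumulants
  theory <- mean_deviation_trajectory(traj$delta_c1[1], c2_0, reg$s,
                                      traj$generation)
  rel <- abs(traj$delta_c1 - theory) / abs(theory)
  expect_lt(max(rel), 0.05)
})

test_that("the exponential law solves the constant-variance mean ODE", {
  # RK4 integration of d(delta)/dt = -s * c2 * delta with constant c2
  s <- 0.1; c2 <- 0.0089; d0 <- -0.303
  f <- function(d) -s * c2 * d
  d <- d0
  dt <- 1
  rk4_path <- numeric(5000)
  for (t in 1:5000) {
    k1 <- f(d); k2 <- f(d + dt * k1 / 2)
    k3 <- f(d + dt * k2 / 2); k4 <- f(d + dt * k3)
    d <- d + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    rk4_path[t] <- d
  }
  expect_lt(max(abs(rk4_path -
                      mean_deviation_trajectory(d0, c2, s, 1:5000))), 1e-8)
})

test_that("drift-free dynamics move all frequencies coherently toward the optimum", {
  set.seed(14)
  # effects bounded away from zero so that directional selection dominates
  # the (tiny) mutational flux everywhere
  arch <- trait_architecture(30, effects = runif(30, 0.005, 0.02), mu = 1e-6)
  reg <- selection_regime(0.1, z_initial = 0.01, z_final = 0.2)
  p0 <- runif(30, 0.2, 0.8)
  traj <- integrate_deterministic(p0, arch, reg, 500)
  # while the mean is clearly below the new optimum, no frequency decreases
  below <- which(traj$cumulants$delta_c1 < -0.05)
  below <- below[below < nrow(traj$freqs)]
  steps <- traj$freqs[below + 1L, ] - traj$freqs[below, ]
  expect_true(all(steps > -1e-12))
})

test_that("quasi-equilibrium deviation solves the stationarity condition", {
  s <- 0.1; mu <- 1e-5; z0 <- 0.2; c2 <- 0.0089; c3 <- -5e-5
  d <- quasi_equilibrium_deviation(c2, c3, s, mu, z0)
  # root of the mean-dynamics right-hand side with d(delta)/dt = 0
  rhs <- -(s / 2) * c3 - s * c2 * d - 2 * mu * (z0 + d)
  expect_lt(abs(rhs), 1e-12)
  # degenerate and trivial cases
  expect_equal(quasi_equilibrium_deviation(0.01, 0, s, mu, 0), 0)
  expect_error(quasi_equilibrium_deviation(0, 0, 0.1, 0, 0.2), "degenerate")
  # invariant under joint rescaling of s and mu
  expect_equal(d, quasi_equilibrium_deviation(c2, c3, 7 * s, 7 * mu, z0),
               tolerance = 1e-12)
})

test_that("exponential approach law has the right anchor and e-folding", {
  expect_equal(mean_deviation_trajectory(-0.303, 0.0089, 0.1, 0), -0.303)
  tau <- short_term_duration(0.1, 0.0089)
  expect_equal(mean_deviation_trajectory(-0.303, 0.0089, 0.1, tau),
               -0.303 / exp(1))
  # |deviation| falls below 1% of its initial value after log(100)/(s c2)
  t99 <- log(100) / (0.1 * 0.0089)
  expect_lt(abs(mean_deviation_trajectory(-0.303, 0.0089, 0.1, 5175)),
            0.01 * 0.303)
  expect_gt(5175, t99)
  expect_error(mean_deviation_trajectory(-0.3, 0.0089, 0.1, -5),
               "non-negative")
})

test_that("short-term duration scales inversely with variance", {
  expect_equal(short_term_duration(0.1, 0.0089), 1 / 8.9e-4)
  expect_equal(short_term_duration(0.1, 0.0045), 1 / 4.5e-4)
  expect_equal(short_term_duration(0.1, 2 * 0.0089),
               short_term_duration(0.1, 0.0089) / 2)
  expect_error(short_term_duration(0.1, 0), "positive")
})

test_that("moment state enforces the heterozygosity identity and bounds", {
  m <- moment_state(e_p = 0.3, e_p2 = 0.12, e_p2q = 0.05)
  expect_equal(m$e_pq, 0.3 - 0.12)
  expect_error(moment_state(0.3, 0.5, 0.05), "E\\[p")
  expect_error(moment_state(0.3, 0.05, 0.05), "E\\[p")
})

test_that("moment equations: drift-only decay and the pq identity", {
  m <- moment_state(e_p = 0.3, e_p2 = 0.12, e_p2q = 0.05)
  r0 <- moment_rhs(m, gamma = 0.01, s = 0.1, delta_c1 = 0, N = 5000)
  expect_equal(r0$de_p, 0)
  expect_equal(r0$de_pq, -m$e_pq / 10000)
  # d/dt E[pq] == d/dt E[p] - d/dt E[p^2] identically
  set.seed(99)
  for (i in 1:20) {
    e_p <- runif(1)
    e_p2 <- runif(1, e_p^2, e_p)
    m <- moment_state(e_p, e_p2, runif(1, 0, 0.15))
    r <- moment_rhs(m, gamma = rexp(1, 100), s = runif(1, 0, 1),
                    delta_c1 = runif(1, -0.5, 0.5), N = sample(100:10000, 1))
    expect_equal(r$de_pq, r$de_p - r$de_p2, tolerance = 1e-14)
  }
  expect_error(moment_rhs(m, 0.01, 0.1, 0, N = -5), "positive")
})

test_that("moment equations match one-generation ensemble increments", {
  # single locus, large ensemble of Wright-Fisher populations started from a
  # common state; mutation off so that only the terms kept by the
  # directional-selection diffusion act (stabilizing selection is orders of
  # magnitude smaller here)
  g <- 0.01; s <- 0.1; N <- 5000; p0 <- 0.3
  arch <- trait_architecture(1, effects = g, mu = 0, nu = 0)
  # choose the pre-shift optimum so that delta_c1 = -0.3 at p0
  z <- g * (2 * p0 - 1) + 0.3
  reg <- selection_regime(s, z_initial = z, z_final = z)
  n_rep <- 1e5
  set.seed(123)
  p1 <- suppressWarnings(
    wf_step(matrix(p0, 1, n_rep), arch, reg, N = N))
  d0 <- g * (2 * p0 - 1) - z
  m <- moment_state(p0, p0^2, p0^2 * (1 - p0))
  r <- moment_rhs(m, g, s, d0, N)

  inc_p <- mean(p1) - p0
  se_p <- stats::sd(p1) / sqrt(n_rep)
  expect_lt(abs(inc_p - r$de_p), 3 * se_p)

  inc_p2 <- mean(p1^2) - p0^2
  se_p2 <- stats::sd(p1^2) / sqrt(n_rep)
  expect_lt(abs(inc_p2 - r$de_p2), 3 * se_p2)

  pq1 <- p1 * (1 - p1)
  inc_pq <- mean(pq1) - p0 * (1 - p0)
  se_pq <- stats::sd(pq1) / sqrt(n_rep)
  expect_lt(abs(inc_pq - r$de_pq), 3 * se_pq)
})

test_that("short-term frequency shifts are coherent and ordered", {
  arch <- trait_architecture(3, effects = c(0.004, 0.008, 0.01), mu = 1e-5)
  # no deviation or no variation: no shift
  expect_equal(short_term_shift(c(0.3, 0.5, 0.7), arch, 0, 0.0089),
               rep(0, 3))
  expect_equal(short_term_shift(c(0, 1, 0), arch, -0.3, 0.0089), rep(0, 3))
  # shifts share the sign of -delta_c1 and increase with gamma * p * q
  p0 <- c(0.5, 0.5, 0.3)
  d <- short_term_shift(p0, arch, -0.3, 0.0089)
  expect_true(all(d > 0))
  compound <- arch$effects * p0 * (1 - p0)
  expect_equal(order(d), order(compound))
  expect_true(all(short_term_shift(p0, arch, 0.3, 0.0089) < 0))
})

test_that("short-term shifts agree with drift-free integration for small effects", {
  s <- 0.1
  c2_0 <- 0.0089
  d0 <- -0.3
  horizon <- round(1 / (s * c2_0))
  for (g in c(0.002, 0.005, 0.01)) {
    for (p0 in c(0.3, 0.5, 0.7)) {
      arch <- trait_architecture(1, effects = g, mu = 1e-5)
      pred <- short_term_shift(p0, arch, d0, c2_0)
      oracle <- euler_expected_frequency(p0, g, s, d0, c2_0, horizon) - p0
      expect_lt(abs(pred - oracle) / abs(oracle), 0.1)
    }
  }
})
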