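test_that("demography schedules validate and expand correctly", {
  dem <- demography(sizes = c(100, 50), durations = c(10, 5))
  expect_equal(dem$span, 15L)
  expect_equal(polyadapt:::demography_sizes(dem), c(rep(100, 10), rep(50, 5)))
  expect_error(demography(c(100), c(0)), ">= 1")
  expect_error(demography(c(1), c(10)), ">= 2")
  bn <- bottleneck_demography()
  expect_equal(bn$epochs$N, c(2e4, 3000, 2e4, 6e5))
  expect_equal(bn$epochs$duration, c(20000L, 5000L, 500L, 100L))
  # post-equilibrium span: bottleneck starts 5600 generations before present
  expect_equal(sum(bn$epochs$duration[-1]), 5600L)
})

test_that("boundaries are absorbing without mutation", {
  arch <- trait_architecture(2, effects = c(0.01, 0.02), mu = 0, nu = 0)
  reg <- selection_regime(0.1, 0.01)
  set.seed(1)
  for (i in 1:20) {
    out <- wf_step(c(0, 1), arch, reg, N = 100)
    expect_equal(out, c(0, 1))
  }
})

test_that("neutral heterozygosity decays as (1 - 1/2N)^t", {
  N <- 50
  t_end <- 10
  n_rep <- 1e5
  arch <- trait_architecture(1, effects = 0.01, mu = 0, nu = 0)
  reg <- selection_regime(0, 0.001)
  p <- matrix(0.5, 1, n_rep)
  set.seed(21)
  for (t in seq_len(t_end)) p <- wf_step(p, arch, reg, N = N)
  pq <- p * (1 - p)
  want <- 0.25 * (1 - 1 / (2 * N))^t_end
  expect_lt(abs(mean(pq) - want), 3 * stats::sd(pq) / sqrt(n_rep))
})

test_that("one generation of drift has binomial mean and variance", {
  N <- 200
  p0 <- 0.37
  n_rep <- 1e5
  arch <- trait_architecture(1, effects = 0.01, mu = 0, nu = 0)
  reg <- selection_regime(0, 0.001)
  set.seed(31)
  p1 <- drop(wf_step(matrix(p0, 1, n_rep), arch, reg, N = N))
  se_mean <- stats::sd(p1) / sqrt(n_rep)
  expect_lt(abs(mean(p1) - p0), 3 * se_mean)
  v <- stats::var(p1)
  want_v <- p0 * (1 - p0) / (2 * N)
  se_v <- sqrt((mean((p1 - mean(p1))^4) - v^2) / n_rep)
  expect_lt(abs(v - want_v), 3 * se_v)
})

test_that("ensemble runs are reproducible and replicate-stable under the seed", {
  arch <- trait_architecture(10, mean_effect = 0.01, mu = 1e-4, seed = 2)
  reg <- selection_regime(0.1, 0.02)
  dem <- demography(200, 50)
  a <- simulate_wf(arch, reg, dem, n_replicates = 5, burn_in = 400, seed = 9)
  b <- simulate_wf(arch, reg, dem, n_replicates = 5, burn_in = 400, seed = 9)
  expect_identical(a$summary, b$summary)
  # growing the ensemble must not reshuffle earlier replicates
  c3 <- simulate_wf(arch, reg, dem, n_replicates = 3, burn_in = 400, seed = 9)
  expect_identical(a$final_freqs[, 1:3], c3$final_freqs)
  expect_false(identical(
    a$summary,
    simulate_wf(arch, reg, dem, n_replicates = 5, burn_in = 400,
                seed = 10)$summary))
})

test_that("the stochastic simulator approaches the deterministic limit", {
  arch <- trait_architecture(20, mean_effect = 0.01, mu = 1e-5, seed = 5)
  reg <- selection_regime(0.1, z_initial = 0.02, z_final = 0.1)
  dem <- demography(1e8, 300)
  sim <- simulate_wf(arch, reg, dem, n_replicates = 1, init = "fixed",
                     init_freqs = 0.5, burn_in = 0, seed = 3)
  det <- integrate_deterministic(rep(0.5, 20), arch, reg, 300)
  expect_lt(max(abs(sim$summary$delta_c1 - det$cumulants$delta_c1)), 1e-3)
  expect_lt(max(abs(sim$summary$c2 - det$cumulants$c2)), 1e-4)
})

test_that("constant-size runs are stationary: matched half-window averages", {
  arch <- trait_architecture(50, mean_effect = 0.01, mu = 1e-4, seed = 12)
  reg <- selection_regime(0.1, 0.1)
  span <- 16000L
  dem <- demography(2000, span)
  sim <- simulate_wf(arch, reg, dem, n_replicates = 30, burn_in = 8000,
                     seed = 17, freq_stride = 100L)
  # compare half-means using between-block variation (blocks longer than the
  # relaxation time, so approximately independent)
  blocks <- split(seq_len(span), rep(1:8, each = span / 8))
  for (stat in c("delta_c1", "c2")) {
    bm <- vapply(blocks, function(ix) mean(sim$summary[[stat]][ix + 1L]),
                 numeric(1))
    diff_halves <- mean(bm[1:4]) - mean(bm[5:8])
    pooled_se <- sqrt(stats::var(bm[1:4]) / 4 + stats::var(bm[5:8]) / 4)
    expect_lt(abs(diff_halves), 2.6 * pooled_se)
  }
  # no directional trend in the mean frequency of any effect-size window
  overall <- locus_subset_mean(sim, 0.01, Inf)
  expect_equal(overall$mean_freq, rowMeans(sim$mean_freqs))
  expect_lt(abs(overall$mean_freq[nrow(overall)] - overall$mean_freq[1]),
            0.02)
  expect_error(locus_subset_mean(sim, 10, 0.001), "window")
})

test_that("single-locus occupancy matches the stationary diffusion density", {
  # scaled parameter set preserving the default regime's diffusion exponents
  # (beta = 0.4, alpha * gamma^2 = 0.4, 2 * alpha * gamma * |delta| = 0.18)
  # at a smaller N so that the occupancy chain mixes within the run
  N <- 1000
  mu <- 2e-4
  s <- 0.1
  g <- sqrt(0.4 / (2 * N * s))
  delta <- -0.18 / (2 * 2 * N * s * g)
  arch <- trait_architecture(1, effects = g, mu = mu)
  reg <- selection_regime(s, z_initial = 0.01, z_final = 0.01)
  dem <- demography(N, 4e6)
  sim <- simulate_wf(arch, reg, dem, n_replicates = 1, init = "fixed",
                     init_freqs = 0.5, burn_in = 20000, seed = 41,
                     freq_stride = 4L, delta_c1_fixed = delta)
  occ <- sim$mean_freqs[, 1]
  occ <- occ[occ > 0 & occ < 1]  # the CDF comparison is on the interior
  pars <- stationary_params(N, s, mu, g, delta)
  ks <- ks_distance(occ, function(q) stationary_cdf(q, pars))
  expect_lt(ks, 0.05)
})

test_that("after a shift, alignment holds for intermediate-frequency loci only", {
  # strong-drift population: loci starting at intermediate frequencies align
  # with the optimum shift more often than near-boundary loci
  arch <- trait_architecture(200, mean_effect = 0.01, mu = 1e-5, seed = 6)
  reg <- selection_regime(0.1, z_initial = 0.2, z_final = 0.5)
  N <- 2000
  eq <- solve_equilibrium(arch, selection_regime(0.1, 0.2), N)
  span <- round(short_term_duration(0.1, eq$c2))
  dem <- demography(N, span)
  sim <- simulate_wf(arch, reg, dem, n_replicates = 40, seed = 23)
  dp <- sim$final_freqs - sim$init_freqs
  p0 <- sim$init_freqs
  mid <- p0 >= 0.3 & p0 <= 0.7
  extreme <- p0 < 0.1 | p0 > 0.9
  frac_mid <- mean(dp[mid] > 0)
  frac_extreme <- mean(dp[extreme] > 0)
  expect_gt(frac_mid, frac_extreme)
  expect_gt(frac_mid, 0.5)
})

test_that("trajectory writers round-trip and manifests are complete", {
  arch <- trait_architecture(5, mean_effect = 0.01, mu = 1e-4, seed = 2)
  reg <- selection_regime(0.1, 0.01)
  dem <- demography(100, 20)
  sim <- simulate_wf(arch, reg, dem, n_replicates = 2, burn_in = 100,
                     seed = 4, freq_stride = 5L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(sim, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$delta_c1, sim$summary$delta_c1, tolerance = 1e-12)
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  write_freqs_tsv(sim, ftsv)
  fb <- utils::read.table(ftsv, header = TRUE, sep = "\t")
  expect_equal(nrow(fb), length(sim$freq_generations))
  mf <- withr::local_tempfile(fileext = ".json")
  write_manifest(sim, mf)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  expect_equal(man$seed, 4)
  expect_equal(man$architecture$effects, arch$effects, tolerance = 1e-12)
  expect_equal(man$demography$N, 100)
})
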