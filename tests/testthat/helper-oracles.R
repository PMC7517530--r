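# Independent oracles used across the test files.

# Exact cumulants of the genotypic-value distribution by brute-force
# enumeration of all 3^l diploid genotype combinations under Hardy-Weinberg
# and linkage equilibrium. Feasible for l <= ~8; used to check the closed
# cumulant formulas.
cumulants_brute_force <- function(p, gamma) {
  l <- length(p)
  stopifnot(length(gamma) == l)
  per_locus <- lapply(seq_len(l), function(i) {
    # genotype value at locus i: -gamma, 0, +gamma with HWE weights
    data.frame(value = c(-gamma[i], 0, gamma[i]),
               prob = c((1 - p[i])^2, 2 * p[i] * (1 - p[i]), p[i]^2))
  })
  combo <- expand.grid(lapply(per_locus, function(d) seq_len(3)))
  z <- rowSums(mapply(function(d, idx) d$value[idx], per_locus, combo))
  w <- apply(mapply(function(d, idx) d$prob[idx], per_locus, combo), 1, prod)
  m <- sum(w * z)
  c(c1 = m,
    c2 = sum(w * (z - m)^2),
    c3 = sum(w * (z - m)^3))
}

# Drift-free forward-Euler integration of the expected-frequency equation
# dE[p]/dt = -s * gamma * p * (1 - p) * delta_c1(t), with the mean deviation
# following the exponential approach law. Independent of the package's
# integrators.
euler_expected_frequency <- function(p0, gamma, s, delta_c1_0, c2_0, t_end) {
  p <- p0
  for (t in seq_len(t_end)) {
    d <- delta_c1_0 * exp(-s * c2_0 * (t - 1))
    p <- p - s * gamma * p * (1 - p) * d
  }
  p
}

# Kolmogorov-Smirnov distance between a sample and a cdf function
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  fx <- cdf(x)
  max(abs(fx - seq_len(n) / n), abs(fx - (seq_len(n) - 1) / n))
}

# the default study regime used by several files
default_study_regime <- function() selection_regime(s = 0.1, z_initial = 0.2)
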