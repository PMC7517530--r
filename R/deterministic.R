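# Deterministic and moment-level dynamics: per-locus selection-mutation
# velocity, forward-Euler integration, the quasi-equilibrium lag of the trait
# mean behind the optimum, the exponential approach law after an optimum
# shift, the moment ODEs of the allele-frequency diffusion, and the
# deterministic short-term frequency shift.

#' Deterministic per-generation change of allele frequencies
#'
#' The infinite-population change at locus \eqn{i} is
#' \deqn{\dot p_i = -s\gamma_i p_i q_i \Delta c_1
#'   - \tfrac{s\gamma_i^2}{2} p_i q_i (q_i - p_i) - \mu p_i + \nu q_i,}
#' the three contributions being directional selection toward the optimum
#' (coupled through the deviation \eqn{\Delta c_1} of the mean from the
#' current optimum), stabilizing selection, and mutational flux.
#'
#' @param freqs Frequencies: vector, [population_state()], or matrix
#'   (loci in rows).
#' @param arch A [trait_architecture()].
#' @param regime A [selection_regime()] (only `s` is used).
#' @param delta_c1 Deviation of the trait mean from the current optimum,
#'   \eqn{c_1 - z_{opt}}. For matrix input, a vector with one entry per
#'   column is recycled across loci.
#' @return Per-locus frequency changes, with the shape of `freqs`.
#' @examples
#' arch <- trait_architecture(1, effects = 0.01, mu = 1e-5)
#' reg <- selection_regime(s = 0.1, z_initial = 0.2)
#' allele_velocity(0.3, arch, reg, delta_c1 = -0.3)
#' @export
allele_velocity <- function(freqs, arch, regime, delta_c1) {
  stopifnot(inherits(arch, "trait_architecture"),
            inherits(regime, "selection_regime"))
  p <- as_freq_matrix(freqs, arch$n_loci)
  if (!length(delta_c1) %in% c(1L, ncol(p))) {
    abort("`delta_c1` must be scalar or have one entry per population")
  }
  g <- arch$effects
  s <- regime$s
  q <- 1 - p
  pq <- p * q
  d <- matrix(delta_c1, nrow = nrow(p), ncol = ncol(p), byrow = TRUE)
  v <- -s * g * pq * d - (s * g^2 / 2) * pq * (q - p) -
    arch$mu * p + arch$nu * q
  if (is.matrix(freqs)) v else drop(v)
}

#' Integrate the deterministic allele-frequency dynamics
#'
#' Forward-Euler integration with one generation per step. Each generation
#' the mean deviation \eqn{\Delta c_1 = c_1 - z_{opt}(t)} is recomputed from
#' the current frequencies, the velocity is applied, and frequencies are
#' clipped to \[0, 1\] (a numerical guard only: with positive mutation rates
#' the flow is inward at the boundaries).
#'
#' @param freqs Initial frequencies (vector or [population_state()]; a
#'   `population_state`'s generation stamp sets the starting time relative to
#'   the optimum shift).
#' @param arch A [trait_architecture()].
#' @param regime A [selection_regime()].
#' @param n_generations Number of generations to integrate (>= 0).
#' @return An object of class `det_trajectory`: list with `cumulants`
#'   (tibble with columns `generation`, `c1`, `c2`, `c3`, `z_opt`,
#'   `delta_c1`), `freqs` (matrix, one row per recorded generation), and
#'   `final` (a [population_state()]).
#' @examples
#' arch <- trait_architecture(10, effects = rep(0.01, 10), mu = 1e-5)
#' reg <- selection_regime(s = 0.1, z_initial = 0.001, z_final = 0.05)
#' traj <- integrate_deterministic(rep(0.5, 10), arch, reg, 100)
#' tail(tidy(traj))
#' @export
integrate_deterministic <- function(freqs, arch, regime, n_generations) {
  stopifnot(inherits(arch, "trait_architecture"),
            inherits(regime, "selection_regime"))
  assert_scalar_num(n_generations, "n_generations", nonneg = TRUE)
  n_generations <- as.integer(n_generations)
  t0 <- if (inherits(freqs, "population_state")) freqs$generation else 0L
  p <- drop(as_freq_matrix(freqs, arch$n_loci))

  gens <- t0 + 0:n_generations
  freq_mat <- matrix(NA_real_, nrow = n_generations + 1L, ncol = arch$n_loci)
  c1 <- c2 <- c3 <- numeric(n_generations + 1L)
  g <- arch$effects
  for (k in seq_len(n_generations + 1L)) {
    q <- 1 - p
    pq <- p * q
    c1[k] <- sum(g * (2 * p - 1))
    c2[k] <- sum(2 * g^2 * pq)
    c3[k] <- sum(2 * g^3 * pq * (q - p))
    freq_mat[k, ] <- p
    if (k > n_generations) break
    t <- gens[k]
    d <- c1[k] - optimum_at(regime, t)
    v <- -regime$s * g * pq * d - (regime$s * g^2 / 2) * pq * (q - p) -
      arch$mu * p + arch$nu * q
    p <- pmin(pmax(p + v, 0), 1)
  }
  zopt <- optimum_at(regime, gens)
  structure(
    list(
      cumulants = tibble(generation = gens, c1 = c1, c2 = c2, c3 = c3,
                         z_opt = zopt, delta_c1 = c1 - zopt),
      freqs = freq_mat,
      final = population_state(p, generation = max(gens))
    ),
    class = "det_trajectory"
  )
}

#' @export
tidy.det_trajectory <- function(x, ...) x$cumulants

#' @export
print.det_trajectory <- function(x, ...) {
  n <- nrow(x$cumulants)
  cat(sprintf("<det_trajectory> %d generations, %d loci; final delta_c1 = %.4g\n",
              n - 1L, ncol(x$freqs), x$cumulants$delta_c1[n]))
  invisible(x)
}

#' Quasi-equilibrium deviation of the trait mean from the optimum
#'
#' At stationarity the mean is a fast variable relative to the allele
#' frequencies; setting its rate of change to zero yields the lag
#' \deqn{\tilde{\Delta c_1} = -\frac{(s/2)\,c_3 + 2\mu z_0}{s\,c_2 + 2\mu}.}
#' The skewness term \eqn{c_3} may be neglected when effect sizes are very
#' small; it is included by default.
#'
#' @param c2 Equilibrium genetic variance (>= 0).
#' @param c3 Equilibrium third cumulant (set to 0 to neglect skewness).
#' @param s Selection strength.
#' @param mu Symmetric mutation rate.
#' @param z0 Position of the fitness optimum.
#' @return The quasi-equilibrium mean deviation (trait units). Vectorized
#'   over its arguments.
#' @examples
#' quasi_equilibrium_deviation(c2 = 0.0089, c3 = -5e-5, s = 0.1,
#'                             mu = 1e-5, z0 = 0.2)
#' @export
quasi_equilibrium_deviation <- function(c2, c3, s, mu, z0) {
  if (any(c2 < 0)) abort("`c2` must be non-negative")
  denom <- s * c2 + 2 * mu
  if (any(denom == 0)) {
    abort("degenerate input: s * c2 + 2 * mu must be non-zero")
  }
  -((s / 2) * c3 + 2 * mu * z0) / denom
}

#' Exponential approach of the trait mean to a shifted optimum
#'
#' After a sudden optimum shift the mean deviation decays approximately
#' exponentially at a rate proportional to the pre-shift genetic variance:
#' \eqn{\Delta c_1(t) = \Delta c_1(0)\, e^{-s c_2(0) t}} (Lande's classical
#' response law; here \eqn{c_2(0)} is the stochastic equilibrium variance,
#' which carries the drift effect).
#'
#' @param delta_c1_0 Initial deviation from the new optimum,
#'   \eqn{c_1(0) - z_f}.
#' @param c2_0 Genetic variance at the time of the shift.
#' @param s Selection strength.
#' @param t Generations since the shift (vectorized).
#' @return Predicted deviation(s) at `t`.
#' @examples
#' mean_deviation_trajectory(-0.303, 0.0089, 0.1, t = c(0, 1000, 5000))
#' @export
mean_deviation_trajectory <- function(delta_c1_0, c2_0, s, t) {
  if (any(t < 0)) abort("`t` must be non-negative")
  delta_c1_0 * exp(-s * c2_0 * t)
}

#' Duration of the short-term phase of polygenic adaptation
#'
#' The short-term phase - during which the mean closes most of the gap to the
#' new optimum - lasts about \eqn{1/(s\,c_2(0))} generations.
#'
#' @inheritParams mean_deviation_trajectory
#' @return E-folding time of the mean deviation, in generations.
#' @examples
#' short_term_duration(0.1, 0.0089)
#' @export
short_term_duration <- function(s, c2_0) {
  if (any(s * c2_0 <= 0)) {
    abort("degenerate input: s * c2_0 must be positive")
  }
  1 / (s * c2_0)
}

#' Bundle allele-frequency moments for the diffusion moment equations
#'
#' Stores \eqn{E[p]}, \eqn{E[p^2]} and \eqn{E[p^2 q]}; the heterozygosity
#' moment \eqn{E[pq] = E[p] - E[p^2]} is derived, never stored independently.
#'
#' @param e_p Expected frequency, in \[0, 1\].
#' @param e_p2 Expected squared frequency; must satisfy
#'   \eqn{E[p]^2 \le E[p^2] \le E[p]}.
#' @param e_p2q The third-order moment \eqn{E[p^2(1-p)]}. The moment
#'   hierarchy does not close, so this input is estimated by the caller
#'   (e.g. empirically from an ensemble).
#' @return An object of class `moment_state` with fields `e_p`, `e_p2`,
#'   `e_pq`, `e_p2q`.
#' @export
moment_state <- function(e_p, e_p2, e_p2q) {
  assert_prob(e_p, "e_p")
  assert_prob(e_p2, "e_p2")
  assert_scalar_num(e_p2q, "e_p2q")
  tol <- 1e-12
  if (e_p2 > e_p + tol || e_p2 < e_p^2 - tol) {
    abort("moments must satisfy E[p]^2 <= E[p^2] <= E[p]")
  }
  structure(list(e_p = e_p, e_p2 = e_p2, e_pq = e_p - e_p2, e_p2q = e_p2q),
            class = "moment_state")
}

#' Right-hand sides of the allele-frequency moment equations
#'
#' During the rapid phase after an optimum shift, directional selection
#' dominates stabilizing selection and mutation. The Kolmogorov backward
#' operator of the resulting diffusion yields, for a locus with effect
#' \eqn{\gamma},
#' \deqn{\frac{d}{dt}E[p] = -s\gamma\,E[pq]\,\Delta c_1(t),}
#' \deqn{\frac{d}{dt}E[p^2] = -2s\gamma\,E[p^2 q]\,\Delta c_1(t) +
#'   \frac{E[pq]}{2N},}
#' \deqn{\frac{d}{dt}E[pq] = -s\gamma\,E[pq]\,\Delta c_1(t) +
#'   2s\gamma\,E[p^2 q]\,\Delta c_1(t) - \frac{E[pq]}{2N}.}
#' The hierarchy does not close: \eqn{E[p^2 q]} enters as an input.
#'
#' @param m A [moment_state()].
#' @param gamma Locus effect size.
#' @param s Selection strength.
#' @param delta_c1 Current deviation of the trait mean from the optimum.
#' @param N Diploid population size.
#' @return Named list with elements `de_p`, `de_p2`, `de_pq` (per-generation
#'   rates of change).
#' @examples
#' m <- moment_state(e_p = 0.3, e_p2 = 0.12, e_p2q = 0.05)
#' moment_rhs(m, gamma = 0.01, s = 0.1, delta_c1 = -0.3, N = 5000)
#' @export
moment_rhs <- function(m, gamma, s, delta_c1, N) {
  stopifnot(inherits(m, "moment_state"))
  if (!is.numeric(N) || length(N) != 1L || N <= 0) {
    abort("`N` must be a positive number")
  }
  de_p <- -s * gamma * m$e_pq * delta_c1
  de_p2 <- -2 * s * gamma * m$e_p2q * delta_c1 + m$e_pq / (2 * N)
  de_pq <- -s * gamma * m$e_pq * delta_c1 +
    2 * s * gamma * m$e_p2q * delta_c1 - m$e_pq / (2 * N)
  list(de_p = de_p, de_p2 = de_p2, de_pq = de_pq)
}

#' Deterministic allele-frequency shifts over the short-term phase
#'
#' For sufficiently small effects, the drift-free frequency shift accumulated
#' over the \eqn{1/(s c_2(0))} generations of the short-term phase is
#' \deqn{\delta p_i \approx -\gamma_i\, p_i(0) q_i(0)\,
#'   \frac{\Delta c_1(0)\,(1 - e^{-1})}{c_2(0)}.}
#' All shifts share the sign of \eqn{-\Delta c_1(0)}: after a shift the
#' allele frequencies move coherently in the same direction, with magnitude
#' governed by the compound parameter \eqn{\gamma_i p_i(0) q_i(0)}.
#'
#' @param p0 Initial (pre-shift) frequencies, one per locus.
#' @param arch A [trait_architecture()].
#' @param delta_c1_0 Initial deviation from the new optimum.
#' @param c2_0 Genetic variance at the shift.
#' @return Vector of per-locus frequency shifts.
#' @examples
#' arch <- trait_architecture(3, effects = c(0.005, 0.01, 0.02))
#' short_term_shift(c(0.5, 0.5, 0.5), arch, delta_c1_0 = -0.3, c2_0 = 0.0089)
#' @export
short_term_shift <- function(p0, arch, delta_c1_0, c2_0) {
  stopifnot(inherits(arch, "trait_architecture"))
  p0 <- drop(as_freq_matrix(p0, arch$n_loci))
  if (c2_0 <= 0) abort("`c2_0` must be positive")
  -arch$effects * p0 * (1 - p0) * delta_c1_0 * (1 - exp(-1)) / c2_0
}
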