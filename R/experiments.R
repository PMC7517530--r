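# Experiment presets: stationary-equilibrium measurement, optimum-shift
# response, and bottleneck demography. Defaults encode the standard
# polygenic-architecture parameter set (s = 0.1, l = 200 loci with
# exponential effects of mean 0.01, mu = 1e-5, z0 = 0.2) used throughout the
# package documentation.

experiment_arch <- function(n_loci, mean_effect, effects, mu, seed) {
  if (is.null(effects)) {
    trait_architecture(n_loci, mean_effect = mean_effect, mu = mu,
                       seed = child_seed(seed, 0L))
  } else {
    trait_architecture(length(effects), effects = effects, mu = mu)
  }
}

#' Measure the stationary drift-mutation-selection equilibrium
#'
#' Equilibrates a replicate ensemble at constant size N (initialized from the
#' stationary allele-frequency density, then burned in) and measures the
#' time- and replicate-averaged equilibrium cumulants: the lag
#' \eqn{\tilde{\Delta c_1}} of the trait mean behind the optimum, the genetic
#' variance \eqn{\tilde c_2} and the third cumulant \eqn{\tilde c_3}. The
#' measurement window is the `window` generations after burn-in. The report
#' compares the measurements with the self-consistent theoretical equilibrium
#' and with the quasi-equilibrium lag predicted from the measured cumulants
#' themselves.
#'
#' @param n_loci,mean_effect,effects,mu Trait architecture: either explicit
#'   `effects`, or `n_loci` exponential draws with mean `mean_effect`
#'   (sampled once per experiment and shared by all replicates).
#' @param s Selection strength.
#' @param N Diploid population size.
#' @param z0 Fitness optimum.
#' @param n_replicates Number of replicate populations.
#' @param burn_in Burn-in generations (default 4N).
#' @param window Measurement window after burn-in, in generations.
#' @param seed Master seed.
#' @return An object of class `equilibrium_experiment`; `glance()` gives the
#'   one-row comparison of measurement and theory.
#' @examples
#' \donttest{
#' ex <- run_equilibrium_experiment(n_loci = 50, N = 1000, mu = 1e-4,
#'                                  z0 = 0.05, n_replicates = 10,
#'                                  window = 500, seed = 1)
#' glance(ex)
#' }
#' @export
run_equilibrium_experiment <- function(n_loci = 200L, mean_effect = 0.01,
                                       effects = NULL, s = 0.1, N = 2e4,
                                       mu = 1e-5, z0 = 0.2,
                                       n_replicates = 100L, burn_in = 4 * N,
                                       window = 2000L, seed = 1L) {
  arch <- experiment_arch(n_loci, mean_effect, effects, mu, seed)
  regime <- selection_regime(s = s, z_initial = z0)
  dem <- demography(sizes = N, durations = window)
  stats_fn <- function(c1, c2, c3, gen) {
    c(delta_c1 = mean(c1) - z0, c2 = mean(c2), c3 = mean(c3))
  }
  sim <- simulate_wf(arch, regime, dem, n_replicates = n_replicates,
                     init = "stationary", burn_in = burn_in, seed = seed,
                     replicate_stats = stats_fn)
  rs <- sim$replicate_stats
  est <- vapply(rs[, c("delta_c1", "c2", "c3")], mean, numeric(1))
  se <- vapply(rs[, c("delta_c1", "c2", "c3")], stats::sd,
               numeric(1)) / sqrt(n_replicates)
  measured <- tibble(statistic = c("delta_c1", "c2", "c3"),
                     estimate = unname(est), se = unname(se))
  structure(
    list(
      measured = measured,
      eq8_prediction = quasi_equilibrium_deviation(est[["c2"]], est[["c3"]],
                                                   s, mu, z0),
      theory = glance(sim$equilibrium),
      trajectory = sim,
      config = list(n_loci = arch$n_loci, mean_effect = mean_effect, s = s,
                    N = N, mu = mu, z0 = z0, n_replicates = n_replicates,
                    burn_in = sim$burn_in, window = window, seed = seed)
    ),
    class = "equilibrium_experiment"
  )
}

#' @export
glance.equilibrium_experiment <- function(x, ...) {
  m <- setNames(x$measured$estimate, x$measured$statistic)
  se <- setNames(x$measured$se, x$measured$statistic)
  tibble(
    delta_c1 = m[["delta_c1"]], se_delta_c1 = se[["delta_c1"]],
    c2 = m[["c2"]], se_c2 = se[["c2"]], c3 = m[["c3"]], se_c3 = se[["c3"]],
    eq8_prediction = x$eq8_prediction,
    theory_delta_c1 = x$theory$delta_c1, theory_c2 = x$theory$c2,
    theory_c3 = x$theory$c3
  )
}

#' @export
print.equilibrium_experiment <- function(x, ...) {
  m <- setNames(x$measured$estimate, x$measured$statistic)
  cat(sprintf(
    paste0("<equilibrium_experiment> N = %g, s = %g, %d loci, %d replicates\n",
           "  measured:  delta_c1 = %.4g, c2 = %.4g, c3 = %.3g\n",
           "  theory:    delta_c1 = %.4g, c2 = %.4g, c3 = %.3g (self-consistent)\n",
           "  quasi-equilibrium lag at measured cumulants: %.4g\n"),
    x$config$N, x$config$s, x$config$n_loci, x$config$n_replicates,
    m[["delta_c1"]], m[["c2"]], m[["c3"]],
    x$theory$delta_c1, x$theory$c2, x$theory$c3, x$eq8_prediction))
  invisible(x)
}

#' Simulate the response of the trait mean to a sudden optimum shift
#'
#' Equilibrates at the pre-shift optimum `z0`, shifts the optimum to `zf` at
#' generation 0, and follows the replicate-averaged deviation of the mean
#' from the new optimum through (by default) 1.5 times the expected
#' short-term phase. The returned trajectory carries the exponential-law
#' overlay anchored at the measured initial deviation and variance,
#' \eqn{\Delta c_1(t) = \Delta c_1(0) e^{-s c_2(0) t}}.
#'
#' @inheritParams run_equilibrium_experiment
#' @param zf Post-shift optimum.
#' @param span Number of post-shift generations to follow (default: 1.5
#'   short-term phases, using the theoretical equilibrium variance).
#' @param freq_stride Stride for recording replicate-averaged per-locus
#'   frequencies (for effect-size-windowed summaries).
#' @return An object of class `shift_experiment` with elements `trajectory`
#'   (tibble with `delta_c1` and the `delta_c1_theory` overlay), `delta_c1_0`,
#'   `c2_0`, `short_term` (e-folding time), `sim`, `config`.
#' @export
run_shift_experiment <- function(N = 2e4, n_loci = 200L, mean_effect = 0.01,
                                 effects = NULL, s = 0.1, mu = 1e-5,
                                 z0 = 0.2, zf = 0.5, n_replicates = 200L,
                                 burn_in = 4 * N, span = NULL, seed = 1L,
                                 freq_stride = 25L) {
  arch <- experiment_arch(n_loci, mean_effect, effects, mu, seed)
  regime <- selection_regime(s = s, z_initial = z0, z_final = zf,
                             shift_generation = 0L)
  eq <- solve_equilibrium(arch, selection_regime(s, z0), N)
  if (is.null(span)) span <- ceiling(1.5 * short_term_duration(s, eq$c2))
  dem <- demography(sizes = N, durations = span)
  sim <- simulate_wf(arch, regime, dem, n_replicates = n_replicates,
                     init = "stationary", burn_in = burn_in, seed = seed,
                     freq_stride = freq_stride)
  traj <- sim$summary
  delta0 <- traj$delta_c1[1]
  c2_0 <- traj$c2[1]
  traj$delta_c1_theory <- mean_deviation_trajectory(delta0, c2_0, s,
                                                    traj$generation)
  structure(
    list(
      trajectory = traj, delta_c1_0 = delta0, c2_0 = c2_0,
      short_term = short_term_duration(s, c2_0), sim = sim,
      config = list(N = N, n_loci = arch$n_loci, mean_effect = mean_effect,
                    s = s, mu = mu, z0 = z0, zf = zf,
                    n_replicates = n_replicates, burn_in = sim$burn_in,
                    span = span, seed = seed)
    ),
    class = "shift_experiment"
  )
}

#' @export
tidy.shift_experiment <- function(x, ...) x$trajectory

#' @export
print.shift_experiment <- function(x, ...) {
  cat(sprintf(
    paste0("<shift_experiment> N = %g: optimum %g -> %g\n",
           "  pre-shift: delta_c1(0) = %.4g, c2(0) = %.4g\n",
           "  short-term phase: about %d generations\n"),
    x$config$N, x$config$z0, x$config$zf, x$delta_c1_0, x$c2_0,
    round(x$short_term)))
  invisible(x)
}

#' @export
autoplot.shift_experiment <- function(object, ...) {
  df <- object$trajectory
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$delta_c1,
                                    color = "simulation")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$delta_c1_theory,
                                    color = "exponential law")) +
    ggplot2::labs(x = "generations since optimum shift",
                  y = "deviation of trait mean from new optimum",
                  color = NULL)
}

#' Simulate polygenic adaptation through a population bottleneck
#'
#' Runs the four-epoch bottleneck demography (stationary phase, bottleneck,
#' recovery, recent expansion) for a trait at stationarity, and reports
#' phase-averaged statistics: the lag of the trait mean behind the optimum
#' and the genetic variance, averaged over the last quarter of each phase
#' (and the variance at the final bottleneck generation). Percent changes
#' across the bottleneck are derived from those phase averages.
#'
#' @inheritParams run_equilibrium_experiment
#' @param demography A [bottleneck_demography()]-style schedule whose first
#'   epoch is the stationary phase.
#' @param window_fraction Fraction of each phase (from its end) over which
#'   phase statistics are averaged.
#' @return An object of class `bottleneck_experiment` with elements `phases`
#'   (tibble: phase, N, delta_c1, se_delta_c1, c2, se_c2),
#'   `bottleneck_end_c2` (+ its SE), `pct_delta_c1_increase`, `pct_c2_drop`,
#'   `replicate_stats`, `sim`, `config`.
#' @export
run_bottleneck_experiment <- function(n_loci = 200L, mean_effect = 0.01,
                                      effects = NULL, s = 0.1, mu = 1e-5,
                                      z0 = 0.2, n_replicates = 200L,
                                      demography = bottleneck_demography(),
                                      seed = 1L, window_fraction = 0.25) {
  arch <- experiment_arch(n_loci, mean_effect, effects, mu, seed)
  regime <- selection_regime(s = s, z_initial = z0)
  epochs <- demography$epochs
  n_phase <- nrow(epochs)
  phase_names <- if (n_phase == 4L) {
    c("pre_bottleneck", "bottleneck", "recovery", "expansion")
  } else {
    paste0("phase_", seq_len(n_phase))
  }
  # recorded state indices of the averaging window of each phase: epoch e
  # produces states (start+1)..end; average over the trailing fraction
  windows <- lapply(seq_len(n_phase), function(e) {
    len <- max(1L, floor(epochs$duration[e] * window_fraction))
    seq.int(epochs$end[e] - len + 1L, epochs$end[e]) + 1L  # 1-based index
  })
  bot_end_idx <- epochs$end[min(2L, n_phase)] + 1L
  stats_fn <- function(c1, c2, c3, gen) {
    out <- numeric(0)
    for (e in seq_len(n_phase)) {
      w <- windows[[e]]
      out <- c(out, mean(c1[w]) - z0, mean(c2[w]))
    }
    names(out) <- paste0(rep(phase_names, each = 2L), c("_delta_c1", "_c2"))
    c(out, bottleneck_end_c2 = c2[bot_end_idx])
  }
  sim <- simulate_wf(arch, regime, demography, n_replicates = n_replicates,
                     init = "stationary", burn_in = 0L, seed = seed,
                     replicate_stats = stats_fn)
  rs <- sim$replicate_stats
  col_mean <- function(nm) mean(rs[[nm]])
  col_se <- function(nm) stats::sd(rs[[nm]]) / sqrt(n_replicates)
  phases <- tibble(
    phase = phase_names,
    N = epochs$N,
    delta_c1 = vapply(paste0(phase_names, "_delta_c1"), col_mean, numeric(1)),
    se_delta_c1 = vapply(paste0(phase_names, "_delta_c1"), col_se, numeric(1)),
    c2 = vapply(paste0(phase_names, "_c2"), col_mean, numeric(1)),
    se_c2 = vapply(paste0(phase_names, "_c2"), col_se, numeric(1))
  )
  pre <- phases$delta_c1[1]
  bot <- phases$delta_c1[min(2L, n_phase)]
  structure(
    list(
      phases = phases,
      bottleneck_end_c2 = col_mean("bottleneck_end_c2"),
      se_bottleneck_end_c2 = col_se("bottleneck_end_c2"),
      pct_delta_c1_increase = 100 * (abs(bot) - abs(pre)) / abs(pre),
      pct_c2_drop = 100 * (phases$c2[1] - col_mean("bottleneck_end_c2")) /
        phases$c2[1],
      replicate_stats = rs,
      sim = sim,
      config = list(n_loci = arch$n_loci, mean_effect = mean_effect, s = s,
                    mu = mu, z0 = z0, n_replicates = n_replicates,
                    seed = seed, window_fraction = window_fraction)
    ),
    class = "bottleneck_experiment"
  )
}

#' @export
tidy.bottleneck_experiment <- function(x, ...) x$phases

#' @export
print.bottleneck_experiment <- function(x, ...) {
  cat(sprintf(
    paste0("<bottleneck_experiment> %d replicates\n",
           "  phase-averaged lag: pre = %.4g, bottleneck = %.4g ",
           "(|lag| up %.0f%%)\n",
           "  genetic variance: pre = %.4g, end of bottleneck = %.4g ",
           "(down %.0f%%)\n"),
    x$config$n_replicates, x$phases$delta_c1[1], x$phases$delta_c1[2],
    x$pct_delta_c1_increase, x$phases$c2[1], x$bottleneck_end_c2,
    x$pct_c2_drop))
  invisible(x)
}

#' @export
autoplot.bottleneck_experiment <- function(object, ...) {
  autoplot(object$sim)
}
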