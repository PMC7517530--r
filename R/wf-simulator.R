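# Stochastic forward simulator: per-locus Wright-Fisher binomial resampling
# layered on the deterministic selection + mutation update, with optimum
# shifts, piecewise-constant demography, and replicate ensembles.

#' Piecewise-constant demography schedule
#'
#' An ordered sequence of epochs, each with a duration in generations and a
#' constant diploid population size. The schedule spans the recorded part of
#' a simulation (generation 0 onwards); burn-in runs at the first epoch's
#' size.
#'
#' @param sizes Vector of diploid sizes N (each >= 2).
#' @param durations Vector of epoch durations in generations (each >= 1).
#' @return An object of class `demography_schedule` wrapping a tibble with
#'   columns `epoch`, `duration`, `N`, `start`, `end`.
#' @examples
#' demography(sizes = c(2e4, 3000), durations = c(1000, 5000))
#' @export
demography <- function(sizes, durations) {
  if (length(sizes) != length(durations) || length(sizes) == 0) {
    abort("`sizes` and `durations` must be non-empty vectors of equal length")
  }
  if (any(durations < 1) || any(durations != round(durations))) {
    abort("all epoch durations must be integers >= 1")
  }
  if (any(sizes < 2)) abort("all population sizes must be >= 2")
  ends <- cumsum(durations)
  epochs <- tibble(
    epoch = seq_along(sizes),
    duration = as.integer(durations),
    N = as.numeric(sizes),
    start = c(0L, utils::head(ends, -1L)),
    end = as.integer(ends)
  )
  structure(list(epochs = epochs, span = sum(as.integer(durations))),
            class = "demography_schedule")
}

#' @export
print.demography_schedule <- function(x, ...) {
  cat(sprintf("<demography_schedule> %d epochs spanning %d generations\n",
              nrow(x$epochs), x$span))
  print(x$epochs)
  invisible(x)
}

# population size in effect at each scheduled generation 0..span-1
demography_sizes <- function(dem) {
  rep(dem$epochs$N, dem$epochs$duration)
}

#' Bottleneck demography preset
#'
#' A human-like bottleneck-and-recovery history: a long stationary phase,
#' an instantaneous crash to a small bottleneck size held for thousands of
#' generations, an instantaneous recovery to the stationary size, and a
#' recent dramatic expansion. With the defaults the post-equilibrium span is
#' 5600 generations: the bottleneck starts 5600 generations before present,
#' the recovery 600 generations ago and the expansion 100 generations ago.
#'
#' @param equilibrium_duration Length of the initial stationary phase
#'   (generations).
#' @param equilibrium_N Diploid size during the stationary phase.
#' @param bottleneck_N,bottleneck_duration Size and length of the bottleneck.
#' @param recovery_N,recovery_duration Size and length of the post-bottleneck
#'   recovery phase.
#' @param expansion_N,expansion_duration Size and length of the final
#'   expansion phase.
#' @return A [demography()] schedule with four epochs.
#' @examples
#' bottleneck_demography()
#' @export
bottleneck_demography <- function(equilibrium_duration = 20000,
                                  equilibrium_N = 2e4,
                                  bottleneck_N = 3000,
                                  bottleneck_duration = 5000,
                                  recovery_N = 2e4,
                                  recovery_duration = 500,
                                  expansion_N = 6e5,
                                  expansion_duration = 100) {
  demography(
    sizes = c(equilibrium_N, bottleneck_N, recovery_N, expansion_N),
    durations = c(equilibrium_duration, bottleneck_duration,
                  recovery_duration, expansion_duration)
  )
}

#' One Wright-Fisher generation
#'
#' Applies the deterministic selection + mutation update (clipped to
#' \[0, 1\]) and then resamples 2N gene copies binomially and independently
#' per locus: conditional on the updated frequency \eqn{p^*}, the next
#' generation's frequency has mean \eqn{p^*} and variance
#' \eqn{p^*(1-p^*)/2N}.
#'
#' @param freqs Frequencies: vector, [population_state()], or matrix with one
#'   row per locus and one column per replicate population.
#' @param arch A [trait_architecture()].
#' @param regime A [selection_regime()].
#' @param N Diploid population size.
#' @param t Current generation (sets the optimum via the regime's schedule).
#' @param delta_c1 Optional fixed mean deviation overriding the per-population
#'   value \eqn{c_1 - z_{opt}(t)} (used to hold the mean-field coupling
#'   constant, e.g. in single-locus diffusion checks).
#' @return Next-generation frequencies with the shape of `freqs`.
#' @examples
#' arch <- trait_architecture(5, mean_effect = 0.01, mu = 1e-5, seed = 1)
#' reg <- selection_regime(s = 0.1, z_initial = 0.02)
#' set.seed(1)
#' wf_step(rep(0.5, 5), arch, reg, N = 100)
#' @export
wf_step <- function(freqs, arch, regime, N, t = 0L, delta_c1 = NULL) {
  stopifnot(inherits(arch, "trait_architecture"),
            inherits(regime, "selection_regime"))
  if (!is.numeric(N) || length(N) != 1L || N < 2) abort("`N` must be >= 2")
  p <- as_freq_matrix(freqs, arch$n_loci)
  if (is.null(delta_c1)) {
    delta_c1 <- colSums(arch$effects * (2 * p - 1)) - optimum_at(regime, t)
  }
  ps <- pmin(pmax(p + allele_velocity(p, arch, regime, delta_c1), 0), 1)
  out <- matrix(rbinom(length(ps), size = 2 * N, prob = ps) / (2 * N),
                nrow = nrow(ps))
  if (is.matrix(freqs)) out else drop(out)
}

#' Simulate a replicate ensemble of Wright-Fisher populations
#'
#' Runs `n_replicates` independent populations of `arch$n_loci` unlinked loci
#' through a burn-in at the first epoch's size followed by the full
#' demographic schedule, applying the optimum schedule of `regime`
#' (generation 0 is the first scheduled generation; the optimum shift occurs
#' at `regime$shift_generation`, by convention 0). Each generation the
#' deterministic selection + mutation update is applied with the replicate's
#' own mean deviation (each replicate is one population), followed by
#' independent binomial resampling of 2N gene copies per locus. Fixed loci
#' stay in the system; mutation can re-polymorphize them.
#'
#' Replicate `r` uses a child seed derived deterministically from `seed` and
#' `r`, so increasing `n_replicates` does not reshuffle earlier replicates.
#'
#' @param arch A [trait_architecture()].
#' @param regime A [selection_regime()].
#' @param demography A [demography()] schedule for the recorded span.
#' @param n_replicates Number of independent replicate populations.
#' @param init Either `"stationary"` (per-locus draws from the stationary
#'   density, with the mean deviation from the self-consistent equilibrium
#'   solve at the first epoch's size) or `"fixed"` (all frequencies at
#'   `init_freqs`).
#' @param init_freqs Initial frequency (scalar or per-locus vector) for
#'   `init = "fixed"`.
#' @param burn_in Burn-in length in generations; defaults to 4N at the first
#'   epoch's size. Use a from-scratch burn-in of at least 20N when
#'   initializing from a fixed state.
#' @param seed Master seed (integer).
#' @param freq_stride If > 0, record replicate-averaged per-locus frequencies
#'   every `freq_stride` recorded generations.
#' @param delta_c1_fixed Optional constant mean deviation used in the
#'   directional-selection term instead of each replicate's own
#'   \eqn{c_1 - z_{opt}} (diagnostic use).
#' @param replicate_stats Optional function `f(c1, c2, c3, generation)`
#'   returning a named numeric vector of per-replicate summary statistics; the
#'   inputs are one replicate's recorded trajectories. Results are collected
#'   in the `replicate_stats` tibble of the output.
#' @return An object of class `wf_trajectory`: list with
#'   * `summary`: tibble with one row per recorded generation (0..span),
#'     columns `generation`, `z_opt`, `N`, `delta_c1`, `c2`, `c3`, `sd_c1`,
#'     `sd_c2` (replicate means and between-replicate standard deviations);
#'   * `mean_freqs`: matrix of replicate-averaged per-locus frequencies at
#'     the thinned generations `freq_generations` (or `NULL`);
#'   * `init_freqs`, `final_freqs`: per-replicate frequency matrices
#'     (loci x replicates) at generations 0 and span;
#'   * `replicate_stats`: tibble of per-replicate statistics (or `NULL`);
#'   * run metadata (`n_replicates`, `seed`, `burn_in`, `arch`, `regime`,
#'     `demography`, `equilibrium` - the stationary solve used for
#'     initialization, if any).
#' @examples
#' arch <- trait_architecture(20, mean_effect = 0.01, mu = 1e-4, seed = 1)
#' reg <- selection_regime(s = 0.1, z_initial = 0.05)
#' dem <- demography(sizes = 500, durations = 200)
#' sim <- simulate_wf(arch, reg, dem, n_replicates = 5, burn_in = 1000,
#'                    seed = 1)
#' tail(tidy(sim))
#' @export
simulate_wf <- function(arch, regime, demography, n_replicates = 100L,
                        init = c("stationary", "fixed"), init_freqs = 0.5,
                        burn_in = NULL, seed = 1L, freq_stride = 0L,
                        delta_c1_fixed = NULL, replicate_stats = NULL) {
  stopifnot(inherits(arch, "trait_architecture"),
            inherits(regime, "selection_regime"),
            inherits(demography, "demography_schedule"))
  init <- match.arg(init)
  assert_scalar_num(n_replicates, "n_replicates", positive = TRUE)
  n_replicates <- as.integer(n_replicates)
  check_regime_range(regime, arch)

  span <- demography$span
  n_sched <- demography_sizes(demography)
  n_first <- n_sched[1]
  if (is.null(burn_in)) burn_in <- 4 * n_first
  assert_scalar_num(burn_in, "burn_in", nonneg = TRUE)
  burn_in <- as.integer(burn_in)

  # optimum in effect during each update step (burn-in steps run at negative
  # times, hence under the pre-shift optimum for shift_generation >= 0)
  step_times <- seq.int(-burn_in, span - 1L)
  zopt_steps <- optimum_at(regime, step_times)
  nvec <- c(rep(n_first, burn_in), n_sched)
  total <- burn_in + span

  equilibrium <- NULL
  if (init == "stationary") {
    equilibrium <- solve_equilibrium(arch, regime, n_first)
  } else {
    init_freqs <- rep_len(as.numeric(init_freqs), arch$n_loci)
    if (any(init_freqs < 0 | init_freqs > 1)) {
      abort("`init_freqs` must lie in [0, 1]")
    }
  }

  n_rec <- span + 1L
  sum_c1 <- sum_c2 <- sum_c3 <- numeric(n_rec)
  sq_c1 <- sq_c2 <- numeric(n_rec)
  gen_rec <- 0:span
  freq_gens <- NULL
  sum_freqs <- NULL
  if (freq_stride > 0) {
    freq_gens <- gen_rec[seq(1L, n_rec, by = freq_stride)]
    sum_freqs <- matrix(0, nrow = length(freq_gens), ncol = arch$n_loci)
  }
  init_mat <- matrix(NA_real_, arch$n_loci, n_replicates)
  final_mat <- matrix(NA_real_, arch$n_loci, n_replicates)
  rep_stats <- vector("list", n_replicates)
  dfix <- if (is.null(delta_c1_fixed)) NA_real_ else as.numeric(delta_c1_fixed)

  for (r in seq_len(n_replicates)) {
    set.seed(child_seed(seed, r))
    p0 <- if (init == "stationary") {
      sample_stationary_arch(arch, n_first, regime$s, equilibrium$delta_c1)
    } else {
      init_freqs
    }
    run <- .wf_run_cpp(p0, arch$effects, regime$s, arch$mu, arch$nu,
                       zopt_steps, nvec, burn_in,
                       as.integer(max(freq_stride, 0L)), dfix)
    sum_c1 <- sum_c1 + run$c1
    sum_c2 <- sum_c2 + run$c2
    sum_c3 <- sum_c3 + run$c3
    sq_c1 <- sq_c1 + run$c1^2
    sq_c2 <- sq_c2 + run$c2^2
    if (freq_stride > 0) sum_freqs <- sum_freqs + run$freqs
    init_mat[, r] <- run$init_freqs
    final_mat[, r] <- run$final_freqs
    if (!is.null(replicate_stats)) {
      rep_stats[[r]] <- replicate_stats(run$c1, run$c2, run$c3, gen_rec)
    }
  }

  zopt_rec <- optimum_at(regime, gen_rec)
  n_rec_sizes <- c(n_sched, n_sched[span])[gen_rec + 1L]
  mean_c1 <- sum_c1 / n_replicates
  var_c1 <- pmax(sq_c1 / n_replicates - mean_c1^2, 0)
  mean_c2 <- sum_c2 / n_replicates
  var_c2 <- pmax(sq_c2 / n_replicates - mean_c2^2, 0)
  summary <- tibble(
    generation = gen_rec,
    z_opt = zopt_rec,
    N = n_rec_sizes,
    delta_c1 = mean_c1 - zopt_rec,
    c2 = mean_c2,
    c3 = sum_c3 / n_replicates,
    sd_c1 = sqrt(var_c1 * n_replicates / max(n_replicates - 1L, 1L)),
    sd_c2 = sqrt(var_c2 * n_replicates / max(n_replicates - 1L, 1L))
  )
  stats_tbl <- NULL
  if (!is.null(replicate_stats)) {
    stats_tbl <- dplyr::bind_rows(lapply(rep_stats, function(x) as_tibble(as.list(x))))
    stats_tbl <- dplyr::mutate(stats_tbl, replicate = dplyr::row_number(),
                               .before = 1L)
  }
  structure(
    list(
      summary = summary,
      mean_freqs = if (freq_stride > 0) sum_freqs / n_replicates else NULL,
      freq_generations = freq_gens,
      init_freqs = init_mat,
      final_freqs = final_mat,
      replicate_stats = stats_tbl,
      n_replicates = n_replicates,
      seed = as.integer(seed),
      burn_in = burn_in,
      arch = arch,
      regime = regime,
      demography = demography,
      equilibrium = equilibrium
    ),
    class = "wf_trajectory"
  )
}

#' @export
print.wf_trajectory <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf(
    "<wf_trajectory> %d replicates x %d loci, %d recorded generations (burn-in %d)\n  final delta_c1 = %.4g, c2 = %.4g\n",
    x$n_replicates, x$arch$n_loci, n - 1L, x$burn_in,
    x$summary$delta_c1[n], x$summary$c2[n]))
  invisible(x)
}

#' @export
tidy.wf_trajectory <- function(x, ...) x$summary

#' @export
glance.wf_trajectory <- function(x, ...) {
  n <- nrow(x$summary)
  tibble(
    n_replicates = x$n_replicates, n_loci = x$arch$n_loci,
    span = n - 1L, burn_in = x$burn_in, seed = x$seed,
    final_delta_c1 = x$summary$delta_c1[n], final_c2 = x$summary$c2[n]
  )
}

#' @export
autoplot.wf_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$summary[, c("generation", "delta_c1", "c2")],
    cols = c("delta_c1", "c2"), names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), ncol = 1L,
                        scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL)
}

#' Mean frequency trajectory of loci in an effect-size window
#'
#' Averages the replicate-averaged per-locus frequencies over the loci whose
#' effect sizes fall within `tolerance` of `effect_center` (e.g. "loci with
#' effect size around 0.01"). Requires the simulation to have recorded
#' per-locus means (`freq_stride > 0`).
#'
#' @param trajectory A [simulate_wf()] result with recorded frequencies.
#' @param effect_center Center of the effect-size window.
#' @param tolerance Half-width of the window; `Inf` selects all loci.
#' @return Tibble with columns `generation`, `mean_freq`, `n_loci`.
#' @export
locus_subset_mean <- function(trajectory, effect_center, tolerance) {
  stopifnot(inherits(trajectory, "wf_trajectory"))
  if (is.null(trajectory$mean_freqs)) {
    abort("per-locus means were not recorded; rerun with `freq_stride > 0`")
  }
  sel <- abs(trajectory$arch$effects - effect_center) <= tolerance
  if (!any(sel)) {
    abort("no locus falls in the requested effect-size window")
  }
  tibble(
    generation = trajectory$freq_generations,
    mean_freq = rowMeans(trajectory$mean_freqs[, sel, drop = FALSE]),
    n_loci = sum(sel)
  )
}

#' Write simulation outputs as TSV tables and a JSON run manifest
#'
#' `write_trajectory_tsv()` writes the per-generation summary (generation,
#' delta_c1, c2, c3, z_opt, N); `write_freqs_tsv()` the replicate-averaged
#' per-locus frequencies; `write_manifest()` a JSON manifest with parameters,
#' seed and package version, sufficient to re-run the simulation
#' bit-identically.
#'
#' @param trajectory A [simulate_wf()] result.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "wf_trajectory"))
  df <- as.data.frame(trajectory$summary[
    , c("generation", "delta_c1", "c2", "c3", "z_opt", "N")])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(trajectory)
}

#' @rdname write_trajectory_tsv
#' @export
write_freqs_tsv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "wf_trajectory"))
  if (is.null(trajectory$mean_freqs)) {
    abort("per-locus means were not recorded; rerun with `freq_stride > 0`")
  }
  df <- as.data.frame(trajectory$mean_freqs)
  names(df) <- paste0("locus_", seq_len(ncol(df)))
  df <- cbind(generation = trajectory$freq_generations, df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(trajectory)
}

#' @rdname write_trajectory_tsv
#' @export
write_manifest <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "wf_trajectory"))
  manifest <- list(
    package = "polyadapt",
    version = as.character(utils::packageVersion("polyadapt")),
    seed = trajectory$seed,
    n_replicates = trajectory$n_replicates,
    burn_in = trajectory$burn_in,
    architecture = list(
      n_loci = trajectory$arch$n_loci,
      effects = trajectory$arch$effects,
      mu = trajectory$arch$mu,
      nu = trajectory$arch$nu
    ),
    regime = unclass(trajectory$regime),
    demography = as.data.frame(
      trajectory$demography$epochs[, c("duration", "N")])
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(trajectory)
}
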