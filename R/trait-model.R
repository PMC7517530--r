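# Core domain types: trait architecture, selection regime, population state,
# trait cumulants and Gaussian stabilizing fitness.

#' Define the genetic architecture of an additive polygenic trait
#'
#' The trait is perfectly heritable and controlled additively (no dominance,
#' no epistasis) by `n_loci` unlinked diallelic loci. The trait-increasing
#' (+) allele at locus \eqn{i} contributes \eqn{+\gamma_i/2} to the phenotype
#' and the - allele \eqn{-\gamma_i/2}, so a homozygote spans
#' \eqn{[-\gamma_i, +\gamma_i]}. Alleles mutate recurrently: + to - at rate
#' `mu` and - to + at rate `nu` per generation (equal rates by default, as the
#' stationary theory assumes).
#'
#' Effect sizes may be supplied explicitly via `effects`, or sampled i.i.d.
#' from an exponential distribution with mean `mean_effect` (the standard
#' assumption for polygenic trait architectures). Experiment presets sample
#' one architecture per experiment and reuse it across replicates, so that
#' replicate averaging is over drift realizations, not architectures.
#'
#' @param n_loci Number of loci (positive integer).
#' @param effects Optional numeric vector of per-locus effect sizes
#'   \eqn{\gamma_i} (phenotypic units, strictly positive). Overrides sampling.
#' @param mean_effect Mean effect size \eqn{\bar\gamma} used to sample
#'   exponential effects when `effects` is not given.
#' @param mu Mutation rate from the + to the - allele, per generation.
#' @param nu Mutation rate from the - to the + allele; defaults to `mu`.
#' @param seed Optional seed used when effects are sampled.
#' @return An object of class `trait_architecture`: a list with elements
#'   `n_loci`, `effects`, `mean_effect`, `mu`, `nu`.
#' @examples
#' arch <- trait_architecture(200, mean_effect = 0.01, mu = 1e-5, seed = 1)
#' arch
#' @export
trait_architecture <- function(n_loci, effects = NULL, mean_effect = NULL,
                               mu = 1e-5, nu = mu, seed = NULL) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1 ||
      n_loci != round(n_loci)) {
    abort("`n_loci` must be a positive integer")
  }
  n_loci <- as.integer(n_loci)
  assert_prob(mu, "mu")
  assert_prob(nu, "nu")
  if (is.null(effects)) {
    if (is.null(mean_effect)) {
      abort("supply either `effects` or `mean_effect`")
    }
    effects <- sample_effects(n_loci, mean_effect, seed = seed)
  } else {
    effects <- as.numeric(effects)
    if (length(effects) != n_loci) {
      abort("`effects` must have length `n_loci`")
    }
    if (!all(is.finite(effects)) || any(effects <= 0)) {
      abort("all effect sizes must be strictly positive and finite")
    }
    if (is.null(mean_effect)) mean_effect <- mean(effects)
  }
  structure(
    list(n_loci = n_loci, effects = effects, mean_effect = mean_effect,
         mu = mu, nu = nu),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "<trait_architecture> %d loci, mean effect %.4g (range %.3g-%.3g), mu = %.3g, nu = %.3g\n",
    x$n_loci, mean(x$effects), min(x$effects), max(x$effects), x$mu, x$nu))
  invisible(x)
}

#' Sample exponentially distributed locus effect sizes
#'
#' @param n_loci Number of loci.
#' @param mean_effect Mean of the exponential distribution of effect sizes.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n_loci` positive effect sizes.
#' @examples
#' sample_effects(5, 0.01, seed = 42)
#' @export
sample_effects <- function(n_loci, mean_effect, seed = NULL) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1) {
    abort("`n_loci` must be a positive integer")
  }
  assert_scalar_num(mean_effect, "mean_effect", positive = TRUE)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  rexp(n_loci, rate = 1 / mean_effect)
}

#' Define the stabilizing-selection regime and optimum schedule
#'
#' Fitness is Gaussian in the trait value,
#' \eqn{w(z) = \exp(-\tfrac{s}{2}(z - z_{opt})^2)}, centered on an optimum
#' that jumps from `z_initial` to `z_final` at generation `shift_generation`
#' (by convention the shift happens at generation 0). `1/s` is assumed to be
#' much larger than the phenotypic variance; this is a modeling assumption and
#' is not enforced.
#'
#' @param s Selection strength (inverse squared phenotypic units,
#'   non-negative; `s = 0` gives a neutral trait).
#' @param z_initial Optimum before the shift (\eqn{z_0}).
#' @param z_final Optimum after the shift (\eqn{z_f}); defaults to
#'   `z_initial` (no shift).
#' @param shift_generation Generation at which the optimum jumps.
#' @return An object of class `selection_regime`.
#' @examples
#' selection_regime(s = 0.1, z_initial = 0.2, z_final = 0.5)
#' @export
selection_regime <- function(s, z_initial, z_final = z_initial,
                             shift_generation = 0L) {
  assert_scalar_num(s, "s", nonneg = TRUE)
  assert_scalar_num(z_initial, "z_initial")
  assert_scalar_num(z_final, "z_final")
  assert_scalar_num(shift_generation, "shift_generation")
  structure(
    list(s = s, z_initial = z_initial, z_final = z_final,
         shift_generation = as.integer(shift_generation)),
    class = "selection_regime"
  )
}

#' @export
print.selection_regime <- function(x, ...) {
  cat(sprintf("<selection_regime> s = %g, optimum %g -> %g at generation %d\n",
              x$s, x$z_initial, x$z_final, x$shift_generation))
  invisible(x)
}

# optimum in effect at (vector of) generation(s) t
optimum_at <- function(regime, t) {
  ifelse(t >= regime$shift_generation, regime$z_final, regime$z_initial)
}

# warn when the optimum schedule is outside the range in which the mean can
# track it (0 < z0 and zf < l * mean(gamma))
check_regime_range <- function(regime, arch) {
  zmax <- sum(arch$effects)
  if (regime$z_initial <= 0) {
    warn("`z_initial` should be positive for a stationary mean near the optimum")
  }
  if (regime$z_final >= zmax) {
    warn(sprintf(
      "`z_final` (%.3g) is not below the maximal attainable mean %.3g; the mean cannot reach the optimum",
      regime$z_final, zmax))
  }
  invisible(regime)
}

#' Bundle allele frequencies into a population state
#'
#' @param freqs Vector of trait-increasing allele frequencies, one per locus,
#'   each in \[0, 1\]. The - allele frequency is always derived as `1 - freqs`.
#' @param generation Non-negative integer generation stamp.
#' @return An object of class `population_state`.
#' @export
population_state <- function(freqs, generation = 0L) {
  freqs <- as.numeric(freqs)
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1)) {
    abort("all frequencies must lie in [0, 1]")
  }
  assert_scalar_num(generation, "generation", nonneg = TRUE)
  structure(list(freqs = freqs, generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> %d loci at generation %d, mean frequency %.3f\n",
              length(x$freqs), x$generation, mean(x$freqs)))
  invisible(x)
}

as_freq_matrix <- function(freqs, n_loci) {
  if (inherits(freqs, "population_state")) freqs <- freqs$freqs
  if (is.matrix(freqs)) {
    if (nrow(freqs) != n_loci) {
      abort("frequency matrix must have one row per locus")
    }
    return(freqs)
  }
  freqs <- as.numeric(freqs)
  if (length(freqs) != n_loci) {
    abort("state and architecture have mismatched numbers of loci")
  }
  matrix(freqs, ncol = 1L)
}

#' Trait cumulants from allele frequencies
#'
#' Computes the first three cumulants of the genotypic-value distribution of a
#' randomly mating population (Hardy-Weinberg and linkage equilibrium): the
#' mean \eqn{c_1 = \sum_i \gamma_i (2 p_i - 1)}, the genetic variance
#' \eqn{c_2 = 2 \sum_i \gamma_i^2 p_i q_i} and the third cumulant
#' \eqn{c_3 = 2 \sum_i \gamma_i^3 p_i q_i (q_i - p_i)}, with
#' \eqn{q_i = 1 - p_i}.
#'
#' @param freqs Trait-increasing allele frequencies: a numeric vector, a
#'   [population_state()], or a matrix with one row per locus and one column
#'   per population.
#' @param arch A [trait_architecture()] with matching locus count.
#' @return A tibble with columns `c1`, `c2`, `c3`; one row per population
#'   (column of `freqs`).
#' @examples
#' arch <- trait_architecture(2, effects = c(0.01, 0.02))
#' compute_cumulants(c(0.3, 0.7), arch)
#' @export
compute_cumulants <- function(freqs, arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  p <- as_freq_matrix(freqs, arch$n_loci)
  g <- arch$effects
  q <- 1 - p
  pq <- p * q
  tibble(
    c1 = colSums(g * (2 * p - 1)),
    c2 = colSums(2 * g^2 * pq),
    c3 = colSums(2 * g^3 * pq * (q - p))
  )
}

#' Gaussian stabilizing fitness of a trait value
#'
#' \eqn{w(z) = \exp(-\tfrac{s}{2} (z - z_{opt}(t))^2)}, where the optimum
#' follows the regime's schedule: `z_initial` before `shift_generation` and
#' `z_final` from it onwards.
#'
#' @param z Trait value(s).
#' @param regime A [selection_regime()].
#' @param t Generation(s) at which fitness is evaluated (default 0, i.e.
#'   after the shift under the default convention).
#' @return Fitness value(s) in (0, 1], maximal exactly at the current optimum.
#' @examples
#' reg <- selection_regime(s = 0.1, z_initial = 0.2, z_final = 0.5)
#' fitness(0.5, reg)          # at the new optimum
#' fitness(0.2, reg, t = -1)  # at the old optimum, before the shift
#' @export
fitness <- function(z, regime, t = 0L) {
  stopifnot(inherits(regime, "selection_regime"))
  zopt <- optimum_at(regime, t)
  exp(-(regime$s / 2) * (z - zopt)^2)
}

#' Critical effect size separating small- from large-effect loci
#'
#' Returns \eqn{\hat\gamma = 2\sqrt{2\mu/s}}. Loci with
#' \eqn{\gamma_i < \hat\gamma} behave as small-effect loci (their equilibria
#' are dominated by the mutation-selection-drift balance rather than by
#' directional fixation).
#'
#' @param mu Symmetric per-generation mutation rate.
#' @param s Selection strength.
#' @return The threshold effect size \eqn{\hat\gamma}.
#' @examples
#' threshold_effect(1e-5, 0.1)
#' @export
threshold_effect <- function(mu, s) {
  assert_scalar_num(mu, "mu", positive = TRUE)
  assert_scalar_num(s, "s", positive = TRUE)
  2 * sqrt(2 * mu / s)
}

#' Read or write a trait architecture as a two-column TSV
#'
#' The format has a header row and columns `locus_id` and `effect`.
#' Mutation rates are not part of the table; supply them when reading.
#'
#' @param arch A [trait_architecture()].
#' @param path File path.
#' @return `write_architecture_tsv()` returns `arch` invisibly;
#'   `read_architecture_tsv()` returns a [trait_architecture()].
#' @export
write_architecture_tsv <- function(arch, path) {
  stopifnot(inherits(arch, "trait_architecture"))
  df <- data.frame(locus_id = seq_len(arch$n_loci), effect = arch$effects)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(arch)
}

#' @rdname write_architecture_tsv
#' @param mu,nu Mutation rates to attach to the architecture read from disk.
#' @export
read_architecture_tsv <- function(path, mu = 1e-5, nu = mu) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("locus_id", "effect") %in% names(df))) {
    abort("architecture TSV must have columns `locus_id` and `effect`")
  }
  df <- df[order(df$locus_id), ]
  trait_architecture(nrow(df), effects = df$effect, mu = mu, nu = nu)
}
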