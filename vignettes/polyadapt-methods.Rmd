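---
title: "Models and methods behind polyadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polyadapt` simulates and analyzes the adaptation of a highly polygenic,
perfectly heritable quantitative trait in a population of finite size, under
Gaussian stabilizing selection, symmetric recurrent mutation and random
genetic drift. This vignette explains the model, the numerical methods, the
design decisions that were genuinely open, and what the package's tests do
and do not establish.

## The model

A trait is controlled additively by $l$ unlinked diallelic loci; there is no
dominance, no epistasis, no environmental variance. The trait-increasing (+)
allele at locus $i$ contributes $+\gamma_i/2$ and the $-$ allele
$-\gamma_i/2$, so homozygote values span $[-\gamma_i, +\gamma_i]$. With $p_i$
the frequency of the + allele and $q_i = 1 - p_i$, random mating (Hardy-
Weinberg and linkage equilibrium) gives the first three cumulants of the
genotypic-value distribution

$$c_1 = \sum_i \gamma_i (2p_i - 1), \qquad
  c_2 = 2\sum_i \gamma_i^2 p_i q_i, \qquad
  c_3 = 2\sum_i \gamma_i^3 p_i q_i (q_i - p_i).$$

Fitness is Gaussian about an optimum $z_{\mathrm{opt}}$,
$w(z) = \exp\!\big(-\tfrac{s}{2}(z - z_{\mathrm{opt}})^2\big)$, with $1/s$
much larger than the phenotypic variance. In an effectively infinite
population the per-generation change at locus $i$ is

$$\dot p_i \;=\; -s\gamma_i p_i q_i\,\Delta c_1
  \;-\; \tfrac{s\gamma_i^2}{2} p_i q_i (q_i - p_i)
  \;-\; \mu p_i + \nu q_i,$$

where $\Delta c_1 = c_1 - z_{\mathrm{opt}}$: directional selection coupled
through the mean, stabilizing selection, and mutational flux. The package
assumes symmetric mutation ($\mu = \nu$) wherever stationary theory is
involved. Effect sizes are either supplied or drawn i.i.d. from an
exponential distribution with mean $\bar\gamma$ — the standard assumption for
polygenic architectures. The threshold
$\hat\gamma = 2\sqrt{2\mu/s}$ separates small-effect loci (equilibria shaped
by mutation-selection-drift balance) from large-effect loci; at the default
parameters ($\mu = 10^{-5}$, $s = 0.1$, $\bar\gamma = 0.01$) essentially all
loci are small-effect.

## Stationary equilibrium in a finite population

With drift (diploid size $N$), each locus's frequency follows a diffusion
whose stationary density, for a quasi-constant mean deviation
$\tilde{\Delta c_1}$, is

$$f(p) \;\propto\; p^{2\beta - 1} q^{2\beta - 1}
  \exp\!\big(-2\alpha\gamma\,\tilde{\Delta c_1}\,p - \alpha\gamma^2 pq\big),
  \qquad \alpha = 2Ns,\; \beta = 2N\mu .$$

For $\beta < 1/2$ (the realistic regime: $\beta = 0.4$ at $N = 2\times10^4$,
$\mu = 10^{-5}$) the density is U-shaped and diverges integrably at both
endpoints. At quasi-equilibrium the fast variable $\Delta c_1$ relaxes to

$$\tilde{\Delta c_1} \;\approx\;
  -\frac{(s/2)\,\tilde c_3 + 2\mu z_0}{s\,\tilde c_2 + 2\mu},$$

a small negative lag of the mean behind the optimum. The skewness term can be
neglected for very small effects; the package includes it by default.

**Self-consistency.** $\tilde{\Delta c_1}$ appears inside the density, while
the density's moments determine $\tilde c_2, \tilde c_3$ and hence
$\tilde{\Delta c_1}$. `solve_equilibrium()` closes this loop by damped
fixed-point iteration (default damping 0.7, tolerance $10^{-12}$ on the
change per step; the map is a strong contraction at realistic parameters and
converges in 10–25 iterations). The solved lag also parameterizes the
stationary density used to initialize equilibrium simulations.

### Numerical choices

* **Normalization and moments by Gauss–Jacobi quadrature.** Integrals of the
  form $\int_0^1 p^{2\beta-1} q^{2\beta-1} g(p)\,h(p)\,dp$ are computed with
  a Gauss–Jacobi rule whose weight absorbs the endpoint singularities exactly
  (Golub–Welsch on the symmetric Jacobi recurrence); $g$, the exponential
  tilt, is entire, so 96–400 nodes (scaled with $\alpha\gamma^2$) give
  near-machine accuracy for any $\beta > 0$. The tests cross-check these
  moments against `stats::integrate` under the substitution
  $p = \sin^2\theta$ — two independent routes.
* **The closed-form approximate normalization** (a first-order expansion in
  $\alpha\gamma$ involving the Beta function) is exposed for comparison only
  and is never used as the package's normalizer; it errors when its
  linearization bracket turns non-positive.
* **CDF on a grid.** `stationary_cdf()` accumulates the $\theta$-substituted
  integrand trapezoidally on a fine grid; accuracy is ample for KS-style
  distributional comparisons, which is its purpose.
* **Exact sampling.** `sample_stationary()` uses rejection from a
  Beta($2\beta, 2\beta$) proposal. The log acceptance ratio is a convex
  parabola in $p$, so its maximum sits at an endpoint and the envelope
  constant is closed-form; the sampler is exact arbitrarily close to the
  singular endpoints (a grid inverse-CDF would not be).

## The Wright–Fisher simulator

`simulate_wf()` runs replicate ensembles through a burn-in plus a
piecewise-constant demography. Within a generation the order of events is:
deterministic selection + mutation update (the velocity above, one
generation per Euler step, clipped to $[0,1]$ as a numerical guard), then
binomial resampling of $2N$ gene copies independently per locus — matching
the diffusion's infinitesimal mean and variance
($\mathrm{Var}[\Delta p_i] \approx p_i q_i / 2N$). Unlinked loci justify
per-locus independence; the only coupling is through each replicate's own
$\Delta c_1$, recomputed every generation (each replicate is one
population). Fixed loci stay in the system; mutation can re-polymorphize
them.

* **Compiled core.** The per-replicate loop is C++ (via Rcpp) using R's RNG,
  so `set.seed()` semantics are preserved; replicate $r$ runs under a child
  seed derived deterministically from the master seed and $r$, so growing an
  ensemble never reshuffles earlier replicates.
* **Initialization and burn-in.** Equilibrium runs start from per-locus
  stationary-density draws at the self-consistently solved lag and burn in
  for $4N$ generations by default. A from-scratch mode (`init = "fixed"`)
  exists for validation and should use a much longer burn-in
  ($\gtrsim 20N$).
* **Recording.** Per-generation replicate means (and between-replicate
  standard deviations) of $\Delta c_1, c_2, c_3$; optionally thinned
  replicate-averaged per-locus frequencies, and user-supplied per-replicate
  window statistics (used for honest Monte-Carlo standard errors).

## Response to an optimum shift

When the optimum jumps from $z_0$ to $z_f$ while the population is at
stationarity, the mean closes the gap approximately exponentially,
$\Delta c_1(t) \approx \Delta c_1(0)\,e^{-s c_2(0) t}$ — Lande's response
law, with the *stochastic* equilibrium variance $c_2(0)$ carrying the drift
effect (smaller populations adapt more slowly because they hold less
variance). The short-term phase lasts about $1/(s c_2(0))$ generations.

Underneath, during the rapid phase directional selection dominates and the
Kolmogorov backward operator yields moment equations

$$\tfrac{d}{dt}E[p] = -s\gamma E[pq]\,\Delta c_1(t), \qquad
  \tfrac{d}{dt}E[p^2] = -2s\gamma E[p^2q]\,\Delta c_1(t) + \tfrac{E[pq]}{2N},$$

whose hierarchy does not close ($E[p^2q]$ enters as an input — the package
takes it from the caller, e.g. estimated from an ensemble). Ignoring drift,
integrating the first equation over one short-term phase gives the coherent
per-locus shift
$\delta p_i \approx -\gamma_i p_i(0) q_i(0)\,\Delta c_1(0)(1 - e^{-1})/c_2(0)$,
increasing in the compound parameter $\gamma_i p_i(0) q_i(0)$. With drift,
coherence survives only at intermediate starting frequencies; near-boundary
alleles are drift-dominated and need not stay aligned — the simulator's
ensemble tests verify exactly this contrast.

The validity window of the drift-free shift formula is qualitative
("sufficiently small effects, intermediate frequencies"); the tests pin it
down as: effects $\le 0.01$, starting frequencies in $[0.3, 0.7]$, agreement
within 10% of a drift-free Euler integration. Those numbers are this
package's choices.

## Bottlenecks

`bottleneck_demography()` encodes a human-like four-epoch history: a long
stationary phase at $N = 2\times10^4$ (20,000 generations by default,
configurable), an instantaneous crash to $N = 3000$ held for 5000
generations, recovery to $2\times10^4$ for 500 generations, and a final
expansion to $6\times10^5$ for 100 generations. During the bottleneck drift
erodes $c_2$, and since the equilibrium lag scales like
$\sim 2\mu z_0/(s c_2)$, the mean falls measurably further behind the
optimum; the brief final expansion is far too short to restore variance or
move the mean.

**Phase averaging.** `run_bottleneck_experiment()` summarizes each phase over
its trailing `window_fraction` (default 0.25). The lag keeps deepening
through the 5000-generation bottleneck (its quasi-static endpoint at
$N = 3000$ is several times the pre-bottleneck lag, and the phase is about
one relaxation time long), so trailing-window and whole-phase averages differ
systematically; the acceptance script reports the whole-phase average, which
is what a single "average value during the bottleneck" describes. Both are
available through `window_fraction`.

## Monte-Carlo uncertainty, and what the tests show

The lag statistics are intrinsically noisy: at stationarity $\Delta c_1$
fluctuates with standard deviation $\approx 1/\sqrt{2\cdot 2Ns}$ per
replicate ($\approx 0.016$ at $N = 2\times10^4$; $\approx 0.04$ at
$N = 3000$) around signals of only $0.002$–$0.003$, with autocorrelation
time $\approx 1/(s c_2)$ — comparable to the averaging windows. Replicates
are therefore the only effective averaging axis, and even thousand-replicate
estimates carry 10–25% Monte-Carlo error on the lag. The package's
quantitative tests consequently compare stochastic estimates to their
targets with the stated tolerance *plus three Monte-Carlo standard errors*
of the estimate itself, computed from between-replicate (and
between-architecture) variation; well-resolved statistics such as $c_2$ are
effectively tested at the bare tolerance.

A second, often overlooked, source of spread is the architecture itself: with
200 exponentially distributed effects, the effect-weighted heterozygosity
$\tilde c_2$ varies by about 10% (1 sd) between draws of the architecture.
Equilibrium experiments therefore fix one architecture per experiment
(replicate averaging is over drift realizations), and the acceptance script
averages its reported equilibrium statistics over four independent draws.

**Problem sizes.** The test suite equilibrates $25$–$50$ replicates per
architecture (four architectures) with a $4N$-generation burn-in at
$N = 2\times10^4$ and $N = 5000$, follows 50-replicate shift ensembles for
1300 generations, and runs 600 bottleneck replicates; the acceptance script
uses 100–2000 replicates per quantity. These sizes were chosen so that the
Monte-Carlo error of each tested statistic is small against its tolerance
while a full run stays comfortably interactive.

**Diffusion-quality check at rescaled parameters.** The occupancy-versus-
stationary-density KS test must observe many mixing times (the chain mixes
on the $2N$-generation scale, and U-shaped densities make effective sample
sizes small). It therefore runs at $N = 1000$ for several million
generations with the diffusion invariants $(\beta,\ \alpha\gamma^2,\
2\alpha\gamma|\tilde{\Delta c_1}|)$ matched to the default regime — the
diffusion law depends on the parameters only through these products, so this
is the same test at a tractable mixing time.

## What the generator does and does not emulate

Simulated data reproduce: per-locus mutation–selection–drift equilibria
(including U-shaped frequency distributions), the mean-field coupling of
loci through stabilizing selection, demographic changes, and optimum shifts.
They deliberately omit: linkage and hitchhiking (loci are unlinked and
conditionally independent), the Bulmer-effect reduction of expressed
variance through transient linkage disequilibrium, dominance, epistasis,
pleiotropy, environmental variance, and unequal forward/backward mutation in
the stationary theory. Passing tests therefore validate the model's own
internal consistency and its diffusion-level theory — not the behavior of
real, linked, environmentally noisy genomes.

## Known limitations

* The quasi-equilibrium density treats $\tilde{\Delta c_1}$ as constant;
  the self-consistent solver inherits that approximation (simulated
  equilibria agree with it to a few percent at default parameters).
* The moment hierarchy after a shift does not close; the package exposes the
  right-hand sides rather than pretending to integrate them unaided.
* Lag statistics ($\tilde{\Delta c_1}$ and its bottleneck counterpart) are
  noise-limited; treat any single-experiment value below ~3 Monte-Carlo
  standard errors as indistinguishable from its neighborhood.
* `stationary_cdf()` is a plotting/KS-grade grid evaluation, not a
  quadrature-grade one; use `stationary_moments()` for integrals.
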