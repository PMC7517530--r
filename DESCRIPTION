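Package: polyadapt
Title: Polygenic Adaptation to Shifting Fitness Optima in Finite Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation and diffusion theory for a highly
    polygenic, perfectly heritable quantitative trait under Gaussian stabilizing
    selection, symmetric recurrent mutation and random genetic drift. Provides
    the stationary drift-mutation-selection distribution of allele frequencies
    together with quadrature moments, an exact rejection sampler and a
    self-consistent equilibrium solver; quasi-equilibrium theory for the lag of
    the trait mean behind the fitness optimum; the exponential response of the
    mean to a sudden optimum shift and the moment dynamics of the underlying
    allele frequencies; and replicate ensemble simulation across
    piecewise-constant demographies, including bottleneck scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
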