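Package: ratestab
Title: Rate-Stabilizing Small Area Estimation with Conditional
    Autoregressive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian small area estimation of event rates for
    geographic units with small populations. Fits Besag-York-Mollie
    style conditional autoregressive (CAR) models -- univariate (UCAR),
    multivariate across demographic groups (MCAR), and multivariate
    spatiotemporal (MSTCAR) -- to aggregate event and population counts
    by Markov chain Monte Carlo, with binomial or Poisson likelihoods
    and imputation of privacy-censored cells. Turns posterior samples
    into estimate tables with credible intervals, relative precision,
    levels of reliability, suppression flags, direct age-standardization
    to the 2000 or 2010 US Standard Population, group aggregation,
    comparison against a reference rate, and exceedance probabilities.
    Includes queen/rook polygon contiguity from GeoJSON boundaries,
    GAL neighbor-list input/output, and a synthetic lattice-world
    generator with known true rates for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
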