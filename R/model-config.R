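#' MCMC configuration for the CAR samplers
#'
#' Collects the likelihood family, chain length, seed, and prior
#' hyperparameters used by [fit_ucar()], [fit_mcar()], and [fit_mstcar()].
#' Defaults are standard weakly-informative disease-mapping choices:
#' intercepts `Normal(0, 10^2)`, variances `InverseGamma(0.5, 0.005)`, a
#' `Wishart(G + 1, I)`-scale inverse-Wishart on the between-group
#' covariance, and a uniform prior over a discrete grid for the spatial
#' propriety parameter `rho` (and the temporal autocorrelation in the
#' spatiotemporal model). All are overridable.
#'
#' @param likelihood `"binomial"` (default) with a logit link, or
#'   `"poisson"` with a log link and population offset.
#' @param iterations Total MCMC sweeps.
#' @param burn_in Discarded initial sweeps (`iterations > burn_in`).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer RNG seed; identical seed + input + config
#'   reproduces the draws bit-exactly.
#' @param intercept_sd Prior SD of the intercept(s).
#' @param variance_shape,variance_rate Inverse-gamma shape and rate for the
#'   structured (`tau2`) and unstructured (`sigma2`) variances.
#' @param wishart_df,wishart_scale Inverse-Wishart prior for the
#'   between-group covariance (`NULL`: df = groups + 1, scale = identity).
#' @param rho_grid Support of the discrete uniform prior on the spatial
#'   propriety parameter, values in `[0, 1)`.
#' @param ar_grid Support for the per-group temporal autocorrelation
#'   (spatiotemporal model), values in `[0, 1)`.
#' @param adapt_target Metropolis acceptance rate targeted by the adaptive
#'   random-walk scales during burn-in (frozen afterwards, preserving
#'   detailed balance).
#' @param pin_effects Testing flag: fixes the spatial and heterogeneity
#'   effects at zero and skips their variance updates, reducing the model
#'   to an intercept-only fit.
#' @param rate_gamma_prior Optional `c(shape, rate)` placing a gamma prior
#'   on the single baseline rate `exp(beta)` instead of the normal prior on
#'   `beta` (used with `pin_effects` and a Poisson likelihood, where the
#'   posterior is the closed-form conjugate gamma).
#' @param restricted Flag reserved for restricted-smoothing CAR variants;
#'   not implemented here, errors if set.
#' @param save_effects Keep per-sweep draws of the structured effects
#'   (needed for some diagnostics; modest memory at package scales).
#' @return A `model_config` list.
#' @export
model_config <- function(likelihood = c("binomial", "poisson"),
                         iterations = 6000,
                         burn_in = 2000,
                         thin = 1,
                         seed = 1L,
                         intercept_sd = 10,
                         variance_shape = 0.5,
                         variance_rate = 0.005,
                         wishart_df = NULL,
                         wishart_scale = NULL,
                         rho_grid = c(seq(0, 0.95, by = 0.05), 0.99),
                         ar_grid = seq(0, 0.95, by = 0.05),
                         adapt_target = 0.43,
                         pin_effects = FALSE,
                         rate_gamma_prior = NULL,
                         restricted = FALSE,
                         save_effects = TRUE) {
  likelihood <- match.arg(likelihood)
  if (isTRUE(restricted)) {
    stop(
      "restricted-smoothing CAR variants are not implemented in this package; ",
      "see the restricted-CAR literature for their formulation",
      call. = FALSE
    )
  }
  if (!(iterations > burn_in && burn_in >= 0)) {
    stop("need iterations > burn_in >= 0", call. = FALSE)
  }
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  for (v in c(intercept_sd, variance_shape, variance_rate, adapt_target)) {
    if (!is.finite(v) || v <= 0) stop("prior hyperparameters must be strictly positive", call. = FALSE)
  }
  if (any(rho_grid < 0 | rho_grid >= 1)) stop("rho_grid values must lie in [0, 1)", call. = FALSE)
  if (any(ar_grid < 0 | ar_grid >= 1)) stop("ar_grid values must lie in [0, 1)", call. = FALSE)
  if (!is.null(rate_gamma_prior)) {
    stopifnot(length(rate_gamma_prior) == 2, all(rate_gamma_prior > 0))
  }
  structure(
    list(
      likelihood = likelihood,
      iterations = as.integer(iterations),
      burn_in = as.integer(burn_in),
      thin = as.integer(thin),
      seed = as.integer(seed),
      intercept_sd = intercept_sd,
      variance_shape = variance_shape,
      variance_rate = variance_rate,
      wishart_df = wishart_df,
      wishart_scale = wishart_scale,
      rho_grid = sort(unique(rho_grid)),
      ar_grid = sort(unique(ar_grid)),
      adapt_target = adapt_target,
      pin_effects = isTRUE(pin_effects),
      rate_gamma_prior = rate_gamma_prior,
      save_effects = isTRUE(save_effects)
    ),
    class = "model_config"
  )
}

n_saved_draws <- function(config) {
  (config$iterations - config$burn_in) %/% config$thin
}
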