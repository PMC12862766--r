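#' Fit the univariate CAR (BYM) model
#'
#' Metropolis-within-Gibbs sampler for the two-effect Besag-York-Mollie
#' model on a single region-indexed count vector. The likelihood is
#' `Y_i ~ Binomial(n_i, theta_i)` with `logit(theta_i) = beta + Z_i +
#' eps_i` (or `Y_i ~ Poisson(n_i * theta_i)` with a log link); `Z` carries
#' the intrinsic pairwise-difference CAR prior on the adjacency graph with
#' variance `tau2`, and `eps` is iid mean-zero heterogeneity with variance
#' `sigma2`. Variances get conjugate inverse-gamma Gibbs updates; the
#' effects and intercept use adaptive random-walk Metropolis steps tuned
#' toward the configured acceptance rate during burn-in only. Non-adjacent
#' regions are updated together in graph-coloring blocks, which leaves the
#' full conditionals exact while keeping the sweep vectorized. `Z` is
#' re-centered to sum to zero after every sweep, with the mean absorbed
#' into `beta` so cell rates are untouched. Privacy-censored counts are
#' re-imputed each sweep from the likelihood truncated to
#' `[0, censor_bound - 1]`.
#'
#' @param input A rank-1 `model_input` from [assemble_model_input()] or
#'   [simulate_dataset()].
#' @param config A [model_config()].
#' @return A `rate_samples` object with the thinned post-burn-in rate
#'   draws, imputed-count draws, hyperparameter chains, and per-block
#'   acceptance rates.
#' @seealso [fit_mcar()], [fit_mstcar()], [get_estimates()]
#' @export
fit_ucar <- function(input, config = model_config()) {
  stopifnot(inherits(input, "model_input"))
  if (input$kind != "ucar") stop("fit_ucar requires a ucar model_input", call. = FALSE)
  stopifnot(inherits(config, "model_config"))

  Y0 <- as.vector(input$events[, 1, 1])
  nvec <- as.vector(input$pops[, 1, 1])
  cens <- as.vector(input$censored[, 1, 1])
  bound <- as.vector(input$censor_bound[, 1, 1])
  adj <- input$adjacency
  n <- length(Y0)
  lik <- config$likelihood

  if (lik == "binomial" && any(!cens & Y0 > nvec)) {
    bad <- adj$region_ids[which(!cens & Y0 > nvec)]
    stop(
      "binomial likelihood requires events <= population; violated in: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(nvec == 0)) {
    message(
      "zero-population cell(s) in: ",
      paste(adj$region_ids[nvec == 0], collapse = ", "),
      "; their rates are driven by the prior and neighbors"
    )
  }

  nb <- adj$neighbors
  m <- lengths(nb)
  W <- adjacency_matrix(adj)
  colors <- greedy_coloring(nb)
  classes <- split(seq_len(n), colors)
  edges <- edge_list(nb)
  ncomp <- n_components(nb)

  set.seed(config$seed)

  # initialization
  Ycur <- Y0
  Ycur[cens] <- floor(bound[cens] / 2)
  pooled <- (sum(Ycur) + 0.5) / (sum(nvec) + 1)
  beta <- if (lik == "binomial") stats::qlogis(pooled) else log(pooled)
  Z <- rep(0, n)
  eps <- rep(0, n)
  tau2 <- 1
  sigma2 <- 1
  if (!is.finite(beta) || !is.finite(sum(loglik_term(Ycur, nvec, beta, lik)))) {
    stop("non-finite log-posterior at initialization; check the input data", call. = FALSE)
  }

  pin <- config$pin_effects
  gprior <- config$rate_gamma_prior
  target <- config$adapt_target
  ls_z <- rep(log(0.5), n)
  ls_e <- rep(log(0.5), n)
  ls_b <- log(0.1)

  S <- n_saved_draws(config)
  theta_draws <- matrix(NA_real_, n, S)
  Z_draws <- if (config$save_effects) matrix(NA_real_, n, S) else NULL
  hyper <- matrix(NA_real_, S, 3, dimnames = list(NULL, c("beta", "tau2", "sigma2")))
  n_cens <- sum(cens)
  imputed <- if (n_cens > 0) {
    matrix(NA_real_, n_cens, S, dimnames = list(adj$region_ids[cens], NULL))
  } else {
    NULL
  }
  acc <- c(z = 0, eps = 0, beta = 0)
  acc_n <- c(z = 0, eps = 0, beta = 0)
  save_idx <- 0L

  beta_logprior <- function(b) {
    if (!is.null(gprior)) {
      gprior[1] * b - gprior[2] * exp(b) # gamma prior on exp(beta), Jacobian included
    } else {
      -0.5 * (b / config$intercept_sd)^2
    }
  }

  for (sweep in seq_len(config$iterations)) {
    adapting <- sweep <= config$burn_in
    post <- sweep > config$burn_in

    # censored-count imputation at current rates
    if (n_cens > 0) {
      th_c <- linkinv(beta + Z[cens] + eps[cens], lik)
      Ycur[cens] <- rtrunc_count(th_c, nvec[cens], bound[cens], lik)
    }

    if (!pin) {
      # structured effect, one coloring block at a time
      for (cls in classes) {
        cur <- Z[cls]
        prop <- cur + exp(ls_z[cls]) * stats::rnorm(length(cls))
        nbmean <- as.vector(W[cls, , drop = FALSE] %*% Z) / m[cls]
        lin0 <- beta + cur + eps[cls]
        lin1 <- beta + prop + eps[cls]
        la <- loglik_term(Ycur[cls], nvec[cls], lin1, lik) -
          loglik_term(Ycur[cls], nvec[cls], lin0, lik) -
          0.5 * m[cls] / tau2 * ((prop - nbmean)^2 - (cur - nbmean)^2)
        alpha <- pmin(1, exp(la))
        take <- stats::runif(length(cls)) < alpha
        Z[cls[take]] <- prop[take]
        if (adapting) ls_z[cls] <- ls_z[cls] + adapt_step(sweep) * (alpha - target)
        if (post) {
          acc["z"] <- acc["z"] + sum(take)
          acc_n["z"] <- acc_n["z"] + length(cls)
        }
      }
      # sum-to-zero re-centering, mean absorbed by the intercept
      mu <- mean(Z)
      Z <- Z - mu
      beta <- beta + mu

      # unstructured heterogeneity: cells are conditionally independent
      prop <- eps + exp(ls_e) * stats::rnorm(n)
      lin0 <- beta + Z + eps
      lin1 <- beta + Z + prop
      la <- loglik_term(Ycur, nvec, lin1, lik) - loglik_term(Ycur, nvec, lin0, lik) -
        0.5 / sigma2 * (prop^2 - eps^2)
      alpha <- pmin(1, exp(la))
      take <- stats::runif(n) < alpha
      eps[take] <- prop[take]
      if (adapting) ls_e <- ls_e + adapt_step(sweep) * (alpha - target)
      if (post) {
        acc["eps"] <- acc["eps"] + sum(take)
        acc_n["eps"] <- acc_n["eps"] + n
      }
    }

    # intercept
    bprop <- beta + exp(ls_b) * stats::rnorm(1)
    la <- sum(loglik_term(Ycur, nvec, bprop + Z + eps, lik)) -
      sum(loglik_term(Ycur, nvec, beta + Z + eps, lik)) +
      beta_logprior(bprop) - beta_logprior(beta)
    alpha <- min(1, exp(la))
    btake <- stats::runif(1) < alpha
    if (btake) beta <- bprop
    if (adapting) ls_b <- ls_b + adapt_step(sweep) * (alpha - target)
    if (post) {
      acc["beta"] <- acc["beta"] + btake
      acc_n["beta"] <- acc_n["beta"] + 1
    }

    if (!pin) {
      # conjugate variance updates
      tau2 <- rinvgamma1(
        config$variance_shape + 0.5 * (n - ncomp),
        config$variance_rate + 0.5 * sum((Z[edges[, 1]] - Z[edges[, 2]])^2)
      )
      sigma2 <- rinvgamma1(
        config$variance_shape + 0.5 * n,
        config$variance_rate + 0.5 * sum(eps^2)
      )
    }

    if (post && (sweep - config$burn_in) %% config$thin == 0L) {
      save_idx <- save_idx + 1L
      theta_draws[, save_idx] <- linkinv(beta + Z + eps, lik)
      if (!is.null(Z_draws)) Z_draws[, save_idx] <- Z
      hyper[save_idx, ] <- c(beta, tau2, sigma2)
      if (n_cens > 0) imputed[, save_idx] <- Ycur[cens]
    }
  }

  new_rate_samples(
    theta = array(theta_draws, c(n, 1, 1, S)),
    model = "ucar",
    input = input,
    config = config,
    hyper = tibble::as_tibble(as.data.frame(hyper)),
    effects = if (!is.null(Z_draws)) array(Z_draws, c(n, 1, 1, S)) else NULL,
    imputed = imputed,
    acceptance = ifelse(acc_n > 0, acc / acc_n, NA_real_)
  )
}
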