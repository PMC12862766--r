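#' Fit the multivariate CAR (MCAR) model
#'
#' Extends the spatial smoothing of [fit_ucar()] across demographic
#' groups: each region carries a group-vector spatial effect whose prior
#' is the proper multivariate CAR construction of Gelfand and Vounatsou --
#' conditionally, `Z_i | Z_(-i) ~ N(rho * mean of neighbors,
#' Sigma / m_i)` -- with a between-group covariance `Sigma` under an
#' inverse-Wishart prior and the spatial propriety parameter `rho`
#' sampled over a discrete grid. Group-specific intercepts and iid
#' heterogeneity effects complete the linear predictor as in the
#' univariate model.
#'
#' @param input A rank-2 `model_input` (`kind = "mcar"`).
#' @param config A [model_config()].
#' @return A `rate_samples` object with draws per region and group.
#' @export
fit_mcar <- function(input, config = model_config()) {
  stopifnot(inherits(input, "model_input"))
  if (input$kind != "mcar") stop("fit_mcar requires an mcar model_input", call. = FALSE)
  fit_multicar(input, config, model = "mcar")
}

#' Fit the multivariate spatiotemporal CAR (MSTCAR) model
#'
#' Extends [fit_mcar()] across equally spaced time periods: the
#' group-vector spatial effects follow a first-order autoregression in
#' time with per-group autocorrelation `ar_g` sampled over a discrete
#' grid, and multivariate-CAR innovations. The first period's effects
#' carry the innovation-scale multivariate CAR prior, so a single-period
#' fit reduces exactly to the MCAR model.
#'
#' @param input A rank-3 `model_input` (`kind = "mstcar"`); time periods
#'   must be equally spaced (re-checked here).
#' @param config A [model_config()].
#' @return A `rate_samples` object with draws per region, group, and
#'   period.
#' @export
fit_mstcar <- function(input, config = model_config()) {
  stopifnot(inherits(input, "model_input"))
  if (input$kind != "mstcar") stop("fit_mstcar requires an mstcar model_input", call. = FALSE)
  check_time_spacing(input$time_labels)
  fit_multicar(input, config, model = "mstcar")
}

slice2 <- function(A, t) matrix(A[, , t], dim(A)[1], dim(A)[2])

fit_multicar <- function(input, config, model) {
  Y0 <- input$events
  narr <- input$pops
  cens <- input$censored
  bound <- input$censor_bound
  adj <- input$adjacency
  n <- dim(Y0)[1]
  G <- dim(Y0)[2]
  Tt <- dim(Y0)[3]
  lik <- config$likelihood
  temporal <- Tt > 1

  if (lik == "binomial" && any(!cens & Y0 > narr)) {
    stop("binomial likelihood requires events <= population cell-wise", call. = FALSE)
  }

  nb <- adj$neighbors
  m <- lengths(nb)
  W <- adjacency_matrix(adj)
  classes <- split(seq_len(n), greedy_coloring(nb))
  # eigenvalues of D^-1/2 W D^-1/2 give log|D - rho W| = log|D| + sum log(1 - rho lambda)
  lambda <- eigen(diag(1 / sqrt(m)) %*% W %*% diag(1 / sqrt(m)), symmetric = TRUE, only.values = TRUE)$values

  df0 <- if (is.null(config$wishart_df)) G + 1 else config$wishart_df
  S0 <- if (is.null(config$wishart_scale)) diag(G) else {
    sc <- config$wishart_scale
    if (length(sc) == 1) diag(as.numeric(sc), G) else as.matrix(sc)
  }
  if (nrow(S0) != G || any(eigen((S0 + t(S0)) / 2, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("wishart_scale must be a positive-definite G x G matrix", call. = FALSE)
  }
  rho_grid <- config$rho_grid
  ar_grid <- config$ar_grid

  set.seed(config$seed)

  Ycur <- Y0
  Ycur[cens] <- floor(bound[cens] / 2)
  beta <- matrix(0, G, Tt)
  for (g in seq_len(G)) {
    for (t in seq_len(Tt)) {
      pooled <- (sum(Ycur[, g, t]) + 0.5) / (sum(narr[, g, t]) + 1)
      beta[g, t] <- if (lik == "binomial") stats::qlogis(pooled) else log(pooled)
    }
  }
  if (any(!is.finite(beta))) {
    stop("non-finite log-posterior at initialization; check the input data", call. = FALSE)
  }
  Z <- array(0, c(n, G, Tt))
  eps <- array(0, c(n, G, Tt))
  Sigma <- diag(G)
  Si <- diag(G)
  sigma2 <- rep(1, G)
  rho <- max(rho_grid)
  ar <- rep(ar_grid[ceiling(length(ar_grid) / 2)], G)

  target <- config$adapt_target
  ls_z <- matrix(log(0.5), n, Tt)
  ls_e <- array(log(0.5), c(n, G, Tt))
  ls_b <- matrix(log(0.1), G, Tt)

  S <- n_saved_draws(config)
  theta_draws <- array(NA_real_, c(n, G, Tt, S))
  Z_draws <- if (config$save_effects) array(NA_real_, c(n, G, Tt, S)) else NULL
  hyper_rows <- vector("list", S)
  cens_idx <- which(cens)
  n_cens <- length(cens_idx)
  imputed <- if (n_cens > 0) matrix(NA_real_, n_cens, S) else NULL
  acc <- c(z = 0, eps = 0, beta = 0)
  acc_n <- c(z = 0, eps = 0, beta = 0)
  save_idx <- 0L

  lin_array <- function() {
    out <- Z + eps
    for (t in seq_len(Tt)) out[, , t] <- sweep(slice2(out, t), 2, beta[, t], "+")
    out
  }

  eta_at <- function(t) {
    if (t == 1) {
      slice2(Z, 1)
    } else {
      slice2(Z, t) - sweep(slice2(Z, t - 1), 2, ar, "*")
    }
  }

  for (sweep_i in seq_len(config$iterations)) {
    adapting <- sweep_i <= config$burn_in
    post <- sweep_i > config$burn_in

    if (n_cens > 0) {
      lin <- lin_array()
      th_c <- linkinv(lin[cens_idx], lik)
      Ycur[cens_idx] <- rtrunc_count(th_c, narr[cens_idx], bound[cens_idx], lik)
    }

    # --- structured effects, per period, per coloring block ---
    for (t in seq_len(Tt)) {
      Yt <- slice2(Ycur, t)
      nt <- slice2(narr, t)
      epst <- slice2(eps, t)
      Ztm1a <- if (t > 1) sweep(slice2(Z, t - 1), 2, ar, "*") else NULL
      Ztp1 <- if (t < Tt) slice2(Z, t + 1) else NULL
      for (cls in classes) {
        k <- length(cls)
        eta_t <- eta_at(t)
        St_cls <- (W %*% eta_t)[cls, , drop = FALSE]
        if (t < Tt) {
          eta_tp <- eta_at(t + 1)
          Stp1_cls <- (W %*% eta_tp)[cls, , drop = FALSE]
        }
        prior_part <- function(Zrow) {
          e_t <- if (t == 1) Zrow else Zrow - Ztm1a[cls, , drop = FALSE]
          eSi <- e_t %*% Si
          lp <- -0.5 * m[cls] * rowSums(eSi * e_t) + rho * rowSums(eSi * St_cls)
          if (t < Tt) {
            e_tp <- Ztp1[cls, , drop = FALSE] - sweep(Zrow, 2, ar, "*")
            eSi <- e_tp %*% Si
            lp <- lp - 0.5 * m[cls] * rowSums(eSi * e_tp) + rho * rowSums(eSi * Stp1_cls)
          }
          lp
        }
        cur <- slice2(Z, t)[cls, , drop = FALSE]
        prop <- cur + exp(ls_z[cls, t]) * matrix(stats::rnorm(k * G), k, G)
        lin0 <- sweep(cur + epst[cls, , drop = FALSE], 2, beta[, t], "+")
        lin1 <- sweep(prop + epst[cls, , drop = FALSE], 2, beta[, t], "+")
        ll0 <- rowSums(matrix(loglik_term(Yt[cls, ], nt[cls, ], lin0, lik), k, G))
        ll1 <- rowSums(matrix(loglik_term(Yt[cls, ], nt[cls, ], lin1, lik), k, G))
        la <- ll1 - ll0 + prior_part(prop) - prior_part(cur)
        alpha <- pmin(1, exp(la))
        take <- stats::runif(k) < alpha
        if (any(take)) {
          idx <- cls[take]
          for (g in seq_len(G)) Z[idx, g, t] <- prop[take, g]
        }
        if (adapting) ls_z[cls, t] <- ls_z[cls, t] + adapt_step(sweep_i) * (alpha - target)
        if (post) {
          acc["z"] <- acc["z"] + sum(take)
          acc_n["z"] <- acc_n["z"] + k
        }
      }
    }
    # sum-to-zero re-centering per group-period slice
    for (t in seq_len(Tt)) {
      mu <- colMeans(slice2(Z, t))
      Z[, , t] <- sweep(slice2(Z, t), 2, mu, "-")
      beta[, t] <- beta[, t] + mu
    }

    # --- heterogeneity effects: all cells independent given the rest ---
    lin_z <- Z
    for (t in seq_len(Tt)) lin_z[, , t] <- sweep(slice2(lin_z, t), 2, beta[, t], "+")
    prop <- eps + exp(ls_e) * array(stats::rnorm(n * G * Tt), c(n, G, Tt))
    s2arr <- array(rep(rep(sigma2, each = n), Tt), c(n, G, Tt))
    la <- loglik_term(Ycur, narr, lin_z + prop, lik) -
      loglik_term(Ycur, narr, lin_z + eps, lik) -
      0.5 / s2arr * (prop^2 - eps^2)
    alpha <- pmin(1, exp(la))
    take <- array(stats::runif(n * G * Tt), c(n, G, Tt)) < alpha
    eps[take] <- prop[take]
    if (adapting) ls_e <- ls_e + adapt_step(sweep_i) * (alpha - target)
    if (post) {
      acc["eps"] <- acc["eps"] + sum(take)
      acc_n["eps"] <- acc_n["eps"] + n * G * Tt
    }

    # --- intercepts: disjoint slices, proposed jointly ---
    bprop <- beta + exp(ls_b) * matrix(stats::rnorm(G * Tt), G, Tt)
    for (t in seq_len(Tt)) {
      ze <- slice2(Z, t) + slice2(eps, t)
      Yt <- slice2(Ycur, t)
      nt <- slice2(narr, t)
      ll0 <- colSums(matrix(loglik_term(Yt, nt, sweep(ze, 2, beta[, t], "+"), lik), n, G))
      ll1 <- colSums(matrix(loglik_term(Yt, nt, sweep(ze, 2, bprop[, t], "+"), lik), n, G))
      la <- ll1 - ll0 - 0.5 * ((bprop[, t] / config$intercept_sd)^2 - (beta[, t] / config$intercept_sd)^2)
      alpha <- pmin(1, exp(la))
      take <- stats::runif(G) < alpha
      beta[take, t] <- bprop[take, t]
      if (adapting) ls_b[, t] <- ls_b[, t] + adapt_step(sweep_i) * (alpha - target)
      if (post) {
        acc["beta"] <- acc["beta"] + sum(take)
        acc_n["beta"] <- acc_n["beta"] + G
      }
    }

    # --- conjugate and grid hyperparameter updates ---
    for (g in seq_len(G)) {
      sigma2[g] <- rinvgamma1(
        config$variance_shape + 0.5 * n * Tt,
        config$variance_rate + 0.5 * sum(eps[, g, ]^2)
      )
    }

    Ssum <- matrix(0, G, G)
    for (t in seq_len(Tt)) {
      eta_t <- eta_at(t)
      Qe <- m * eta_t - rho * (W %*% eta_t)
      Ssum <- Ssum + t(eta_t) %*% Qe
    }
    Sigma <- riwish(df0 + n * Tt, S0 + (Ssum + t(Ssum)) / 2)
    Si <- chol2inv(chol(Sigma))
    Si <- (Si + t(Si)) / 2

    if (length(rho_grid) > 1) {
      # W-quadratic under the refreshed Sigma
      trWq <- 0
      for (t in seq_len(Tt)) {
        eta_t <- eta_at(t)
        trWq <- trWq + sum(Si * (t(eta_t) %*% (W %*% eta_t)))
      }
      lp <- (G * Tt / 2) * colSums(log(1 - outer(lambda, rho_grid))) + 0.5 * rho_grid * trWq
      p <- exp(lp - max(lp))
      rho <- rho_grid[sample.int(length(rho_grid), 1, prob = p)]
    }

    if (temporal && length(ar_grid) > 1) {
      for (g in seq_len(G)) {
        lp <- rep(0, length(ar_grid))
        for (t in 2:Tt) {
          u <- Z[, g, t]
          v <- Z[, g, t - 1]
          Qu <- m * u - rho * (W %*% u)
          Qv <- m * v - rho * (W %*% v)
          A <- sum(u * Qu)
          B <- sum(v * Qu)
          C <- sum(v * Qv)
          # cross terms with the other groups' current innovations
          cross_d <- 0
          cross_e <- 0
          if (G > 1) {
            eta_t <- eta_at(t)
            for (h in seq_len(G)[-g]) {
              cross_d <- cross_d + Si[g, h] * sum(eta_t[, h] * Qu)
              cross_e <- cross_e + Si[g, h] * sum(eta_t[, h] * Qv)
            }
          }
          lp <- lp - 0.5 * (Si[g, g] * (A - 2 * ar_grid * B + ar_grid^2 * C) +
            2 * (cross_d - ar_grid * cross_e))
        }
        p <- exp(lp - max(lp))
        ar[g] <- ar_grid[sample.int(length(ar_grid), 1, prob = p)]
      }
    }

    if (post && (sweep_i - config$burn_in) %% config$thin == 0L) {
      save_idx <- save_idx + 1L
      lin <- lin_array()
      theta_draws[, , , save_idx] <- linkinv(lin, lik)
      if (!is.null(Z_draws)) Z_draws[, , , save_idx] <- Z
      hyper_rows[[save_idx]] <- c(
        stats::setNames(as.vector(beta), paste0("beta_", rep(seq_len(G), Tt), "_", rep(seq_len(Tt), each = G))),
        stats::setNames(sigma2, paste0("sigma2_", seq_len(G))),
        {
          ut <- which(upper.tri(Sigma, diag = TRUE), arr.ind = TRUE)
          stats::setNames(
            Sigma[upper.tri(Sigma, diag = TRUE)],
            paste0("Sigma_", ut[, 1], "_", ut[, 2])
          )
        },
        rho = rho,
        stats::setNames(ar, paste0("ar_", seq_len(G)))
      )
      if (n_cens > 0) imputed[, save_idx] <- Ycur[cens_idx]
    }
  }

  hyper <- tibble::as_tibble(as.data.frame(do.call(rbind, hyper_rows)))
  if (n_cens > 0) {
    ai <- which(cens, arr.ind = TRUE)
    rownames(imputed) <- paste(
      adj$region_ids[ai[, 1]], input$group_labels[ai[, 2]], input$time_labels[ai[, 3]],
      sep = "|"
    )
  }

  new_rate_samples(
    theta = theta_draws,
    model = model,
    input = input,
    config = config,
    hyper = hyper,
    effects = Z_draws,
    imputed = imputed,
    acceptance = ifelse(acc_n > 0, acc / acc_n, NA_real_)
  )
}
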