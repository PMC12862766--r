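test_that("multivariate fits are deterministic under a fixed seed", {
  sim <- simulate_dataset(make_lattice(4, 4, "queen"), "mcar",
    params = list(n_groups = 2), seed = 3
  )
  cfg <- model_config(iterations = 400, burn_in = 100, seed = 8)
  f1 <- fit_mcar(sim$input, cfg)
  f2 <- fit_mcar(sim$input, cfg)
  expect_identical(f1$theta, f2$theta)

  sim3 <- simulate_dataset(make_lattice(3, 4, "queen"), "mstcar",
    params = list(n_groups = 2, n_times = 3), seed = 4
  )
  g1 <- fit_mstcar(sim3$input, cfg)
  g2 <- fit_mstcar(sim3$input, cfg)
  expect_identical(g1$theta, g2$theta)
})

test_that("between-group covariance recovers the sign of a strong correlation", {
  # informative populations so the latent fields (and their cross-group
  # covariance) are well identified from the counts
  Sig <- matrix(c(0.3, 0.24, 0.24, 0.3), 2) # correlation 0.8
  sim <- simulate_dataset(make_lattice(7, 7, "queen"), "mcar",
    params = list(n_groups = 2, Sigma = Sig, sigma2 = 0.01, rho = 0.95),
    pop_range = c(5000, 20000), seed = 31
  )
  fit <- fit_mcar(sim$input, model_config(iterations = 3000, burn_in = 1000, seed = 32))
  corr <- fit$hyper$Sigma_1_2 / sqrt(fit$hyper$Sigma_1_1 * fit$hyper$Sigma_2_2)
  expect_gt(mean(corr), 0)
})

test_that("temporal autocorrelation orders correctly against the truth", {
  adj <- make_lattice(4, 4, "queen")
  mk <- function(ar, seed) {
    simulate_dataset(adj, "mstcar",
      params = list(n_groups = 1, n_times = 4, ar = ar, Sigma = matrix(0.3)),
      seed = seed
    )
  }
  cfg <- model_config(iterations = 1500, burn_in = 500, seed = 77)
  fit_hi <- fit_mstcar(mk(0.9, 51)$input, cfg)
  fit_lo <- fit_mstcar(mk(0.0, 52)$input, cfg)
  expect_gt(mean(fit_hi$hyper$ar_1), mean(fit_lo$hyper$ar_1))
})

test_that("a single-period spatiotemporal fit reduces to the multivariate model", {
  sim <- simulate_dataset(make_lattice(4, 4, "queen"), "mcar",
    params = list(n_groups = 2), seed = 21
  )
  inp_m <- sim$input
  inp_t <- sim$input
  inp_t$kind <- "mstcar"
  cfg <- model_config(iterations = 1200, burn_in = 400, seed = 22)
  fm <- fit_mcar(inp_m, cfg)
  ft <- fit_mstcar(inp_t, cfg)
  expect_equal(as.vector(ft$theta), as.vector(fm$theta), tolerance = 1e-12)
})

test_that("a single-group multivariate fit agrees with the univariate model", {
  # matched priors: the 1x1 inverse-Wishart equals the inverse-gamma used
  # by the univariate model, and rho pinned near 1 approximates the
  # intrinsic CAR; equivalence is judged against posterior uncertainty
  sim <- simulate_dataset(make_lattice(6, 6, "queen"), "ucar", seed = 61)
  inp_u <- sim$input
  inp_m <- sim$input
  inp_m$kind <- "mcar"
  fu <- fit_ucar(inp_u, model_config(iterations = 12000, burn_in = 2000, seed = 62))
  fm <- fit_mcar(inp_m, model_config(
    iterations = 12000, burn_in = 2000, seed = 63,
    wishart_df = 1, wishart_scale = 0.01, rho_grid = 0.99
  ))
  mu <- apply(fu$theta[, 1, 1, ], 1, median)
  mm <- apply(fm$theta[, 1, 1, ], 1, median)
  z <- abs(mu - mm) / apply(fu$theta[, 1, 1, ], 1, sd)
  expect_lt(max(z), 0.5)
  expect_lt(mean(z), 0.2)
})

test_that("censored-count imputation honours the truncation bound in a fit", {
  sim <- simulate_dataset(make_lattice(5, 5, "queen"), "ucar",
    censor_bound = 10, seed = 41
  )
  expect_gt(sum(sim$input$censored), 0)
  fit <- fit_ucar(sim$input, model_config(iterations = 1200, burn_in = 400, seed = 42))
  expect_true(all(fit$imputed >= 0 & fit$imputed <= 9))
  # imputation respects the generative truth's support
  expect_true(all(sim$truth$table$true_events[as.vector(sim$input$censored)] < 10))
})

test_that("the imputation step draws from the truncated likelihood", {
  # chi-square goodness of fit against the truncated binomial pmf
  set.seed(8)
  theta <- 0.02
  n <- 400
  bound <- 6
  draws <- impute_censored_step(rep(theta, 20000), n, bound, "binomial")
  expect_true(all(draws >= 0 & draws <= bound - 1))
  pmf <- dbinom(0:(bound - 1), n, theta)
  pmf <- pmf / sum(pmf)
  obs <- tabulate(draws + 1, nbins = bound)
  gof <- suppressWarnings(chisq.test(obs, p = pmf))
  expect_gt(gof$p.value, 0.01)

  # degenerate limit: vanishing rate concentrates imputations at zero
  tiny <- impute_censored_step(rep(1e-9, 500), n, bound, "binomial")
  expect_true(all(tiny == 0))
  expect_error(impute_censored_step(0.1, 100, 0), "positive")
})
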