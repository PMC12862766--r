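test_that("estimates are sample medians with type-7 quantile bounds", {
  s <- fake_samples(matrix(c(1, 2, 3, 4, 5) * 1e-4, nrow = 1))
  est <- suppressWarnings(get_estimates(s, ci_level = 0.95, multiplier = 1e5))
  expect_equal(est$estimate, 30) # 30 per 100,000
  expect_error(get_estimates(s, ci_level = 1.2), "ci_level")

  # large uniform draw set: bounds near the analytic 2.5/97.5 percentiles
  set.seed(1)
  u <- matrix(runif(10000), nrow = 1)
  est_u <- get_estimates(fake_samples(u), ci_level = 0.95, multiplier = 1)
  se_q <- sqrt(0.025 * 0.975 / 10000) # density of U(0,1) is 1
  expect_lt(abs(est_u$lower - 0.025), 3 * se_q)
  expect_lt(abs(est_u$upper - 0.975), 3 * se_q)
})

test_that("degenerate draw sets are maximally precise by convention", {
  s <- fake_samples(matrix(rep(2e-4, 200), nrow = 1))
  est <- suppressWarnings(get_estimates(s))
  expect_equal(est$lower, est$estimate)
  expect_equal(est$upper, est$estimate)
  expect_equal(est$relative_precision, Inf)
  expect_true(est$reliable)
  expect_equal(est$level_of_reliability, 0.99) # top of the default grid
})

test_that("relative precision follows the strict >1 rule and is scale-invariant", {
  expect_equal(relative_precision(2.0, 1.2, 2.8), 1.25)
  expect_true(relative_precision(2.0, 1.2, 2.8) > 1)
  expect_equal(relative_precision(1.0, 0.5, 1.5), 1.0)
  expect_false(relative_precision(1.0, 0.5, 1.5) > 1) # boundary excluded
  expect_equal(
    relative_precision(2e5, 1.2e5, 2.8e5),
    relative_precision(2.0, 1.2, 2.8)
  )
  expect_error(relative_precision(1, 2, 0.5), "below lower")
})

test_that("level of reliability is the top passing grid level, monotone in the grid", {
  # calibrated normal draws: 90% width below the median, 95% width above
  set.seed(2)
  med <- 1
  sd_target <- med / (2 * qnorm(0.96)) # RP crosses 1 between levels 0.90 and 0.95
  draws <- rnorm(50000, mean = med, sd = sd_target)
  lv <- level_of_reliability(draws)
  expect_equal(lv, 0.90)

  # monotone consistency: reliable at the returned level and below
  grid <- c(seq(0.5, 0.95, 0.05), 0.99)
  for (g in grid[grid <= lv]) {
    q <- quantile(draws, c((1 - g) / 2, (1 + g) / 2), names = FALSE)
    expect_gt(relative_precision(median(draws), q[1], q[2]), 1)
  }

  # centered draws can never be reliable
  expect_true(is.na(level_of_reliability(rnorm(5000))))
  expect_error(level_of_reliability(draws, numeric(0)), "empty")
})

test_that("relative precision decreases strictly in the credible level", {
  set.seed(3)
  draws <- rexp(4000, 50)
  med <- median(draws)
  levels <- c(0.5, 0.75, 0.9, 0.95, 0.99)
  rps <- sapply(levels, function(a) {
    q <- quantile(draws, c((1 - a) / 2, (1 + a) / 2), names = FALSE)
    relative_precision(med, q[1], q[2])
  })
  expect_true(all(diff(rps) < 0))
})

test_that("age-standardization is a draw-wise weighted mean", {
  draws <- array(0, c(1, 2, 1, 2))
  draws[1, 1, 1, ] <- c(0.1, 0.12)
  draws[1, 2, 1, ] <- c(0.3, 0.28)
  s <- fake_samples(matrix(draws, 2, 2), groups = c("35-44", "45-54"))
  s$theta <- draws
  std <- tibble::tibble(group = c("35-44", "45-54"), weight = c(0.5, 0.5))
  out <- age_standardize(s, std)
  expect_equal(as.vector(out$theta), c(0.2, 0.2))

  # equal rates in a draw: invariant to the weights
  s$theta[1, 2, 1, ] <- s$theta[1, 1, 1, ]
  out2 <- age_standardize(s, tibble::tibble(group = c("35-44", "45-54"), weight = c(0.9, 0.1)))
  expect_equal(as.vector(out2$theta), as.vector(s$theta[1, 1, 1, ]))

  expect_error(
    age_standardize(s, tibble::tibble(group = "35-44", weight = 1)),
    "45-54"
  )
})

test_that("own-population weights make standardization equal aggregation", {
  set.seed(4)
  s <- fake_samples(matrix(runif(2 * 50, 0.01, 0.05), 2, 50),
    groups = c("g1", "g2"), pops = c(100, 300)
  )
  agg <- aggregate_groups(s)
  std <- age_standardize(s, tibble::tibble(group = c("g1", "g2"), weight = c(100, 300)))
  expect_equal(as.vector(agg$theta), as.vector(std$theta))
})

test_that("group aggregation is the population-weighted draw-wise mean", {
  s <- fake_samples(matrix(c(0.2, 0.1), 2, 1), groups = c("f", "m"), pops = c(100, 300))
  out <- aggregate_groups(s)
  expect_equal(as.vector(out$theta), 0.125)
  expect_equal(as.vector(out$pops), 400)

  # merging a single label is the identity on the draws
  one <- aggregate_groups(s, mapping = list(f = "f", m = "m"))
  expect_equal(as.vector(one$theta), as.vector(s$theta))

  zp <- fake_samples(matrix(c(0.2, 0.1), 2, 1), groups = c("f", "m"), pops = c(0, 0))
  expect_error(aggregate_groups(zp), "zero total population")
  expect_error(aggregate_groups(s, mapping = list(a = "f")), "partition")
})

test_that("sex aggregation then age-standardization composes like the survey workflow", {
  set.seed(5)
  groups <- c("f.35-44", "m.35-44", "f.45-54", "m.45-54")
  s <- fake_samples(matrix(runif(4 * 30, 0.005, 0.02), 4, 30),
    groups = groups, pops = c(120, 110, 200, 180)
  )
  merged <- aggregate_groups(s, mapping = list(
    "35-44" = c("f.35-44", "m.35-44"),
    "45-54" = c("f.45-54", "m.45-54")
  ))
  expect_equal(merged$group_labels, c("35-44", "45-54"))
  out <- age_standardize(merged, standard_population("2000", labels = c("35-44", "45-54")))
  expect_equal(dim(out$theta)[2], 1)
  # the standardized draw is a convex combination of the merged draws
  rng <- apply(matrix(merged$theta[1, , 1, ], 2, 30), 2, range)
  expect_true(all(out$theta[1, 1, 1, ] >= rng[1, ] - 1e-12 & out$theta[1, 1, 1, ] <= rng[2, ] + 1e-12))
})

test_that("suppression flags follow the reliability and population rules", {
  tbl <- tibble::tibble(
    region = c("A", "B", "C"), group = "all", time = "0",
    events = c(20, 25, 30), population = c(150, 80, 500),
    estimate = 1, lower = 0.5, upper = 1.2,
    reliable = c(TRUE, TRUE, FALSE), suppressed = FALSE
  )
  out <- apply_suppression(tbl, pop_threshold = 100)
  expect_equal(out$suppressed, c(FALSE, TRUE, TRUE))
  expect_false(is.na(out$estimate[2])) # flags only, values retained

  crude <- tibble::tibble(events = c(15, 16, NA), rate = c(1, 2, NA))
  out2 <- apply_suppression(crude, event_rule = 16)
  expect_equal(out2$suppressed, c(TRUE, FALSE, TRUE))
  expect_error(apply_suppression(dplyr::select(tbl, -reliable)), "reliable")
})

test_that("classification against a reference follows the credible bounds", {
  tbl <- tibble::tibble(lower = c(1.2, 1.2, 3.1), upper = c(2.8, 2.8, 4.0))
  out <- compare_to_reference(tbl, reference = 3.0)
  expect_equal(out$classification[1], "lower")
  expect_equal(out$classification[3], "higher")
  expect_equal(compare_to_reference(tbl, reference = 2.0)$classification[1], "not_different")
})

test_that("exceedance probabilities count strict exceedances with exact complement", {
  expect_equal(exceedance_probability(c(1, 2, 3, 4), 2.5), 0.5)
  expect_equal(exceedance_probability(c(1, 2, 3, 4), 0), 1.0)
  expect_equal(exceedance_probability(c(1, 2, 3, 4), 9), 0.0)
  expect_equal(exceedance_probability(c(1, 2, 2, 4), 2), 0.25) # ties do not exceed
  set.seed(6)
  for (rep_i in 1:5) {
    d <- rnorm(101)
    v <- rnorm(1)
    expect_identical(exceedance_probability(d, v) + mean(d <= v), 1)
  }
  expect_error(exceedance_probability(numeric(0), 1), "at least one draw")
})

test_that("samples-based comparison is consistent between bounds and exceedance", {
  fit <- default_fit()
  est <- get_estimates(fit)
  ref <- median(est$estimate)
  cmp <- compare_to_reference(fit, reference = ref, ci_level = 0.95)
  hi <- cmp$classification == "higher"
  expect_true(all(cmp$lower[hi] > ref))
  tol <- 3 * sqrt(0.025 * 0.975 / n_draws(fit))
  expect_true(all(cmp$exceedance_probability[hi] >= 0.975 - tol))
})

test_that("crude rates divide events by population with zero-population guards", {
  adj <- adjacency(c("A", "B"), list(2L, 1L))
  inp <- assemble_model_input(
    tibble::tibble(region = c("A", "B"), events = c(16, 0)),
    tibble::tibble(region = c("A", "B"), population = c(3200, 100)),
    adj, "ucar"
  )
  out <- crude_rates(inp)
  expect_equal(out$rate, c(500, 0))

  inp0 <- assemble_model_input(
    tibble::tibble(region = c("A", "B"), events = c(0, 1)),
    tibble::tibble(region = c("A", "B"), population = c(0, 100)),
    adj, "ucar"
  )
  out0 <- crude_rates(inp0)
  expect_true(out0$undefined[1] && is.na(out0$rate[1]))

  inp_bad <- inp0
  inp_bad$events["A", 1, 1] <- 2
  expect_error(crude_rates(inp_bad), "zero population")
})

test_that("all outputs are invariant to the order of the draws", {
  set.seed(7)
  draws <- matrix(rexp(2 * 500, 80), 2, 500)
  s1 <- fake_samples(draws)
  s2 <- fake_samples(draws[, sample(500)])
  e1 <- suppressWarnings(get_estimates(s1))
  e2 <- suppressWarnings(get_estimates(s2))
  expect_equal(e1, e2)
  expect_equal(
    exceedance_probability(s1, 0.01)$exceedance_probability,
    exceedance_probability(s2, 0.01)$exceedance_probability
  )
})
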