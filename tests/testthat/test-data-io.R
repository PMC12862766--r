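test_that("aggregation counts records into cells and conserves totals", {
  rec <- tibble::tibble(region = rep("A", 5))
  out <- aggregate_events(rec, regions = c("A", "B"))
  expect_equal(out$events, c(5L, 0L))

  # conservation under random record sets
  set.seed(42)
  for (rep_i in 1:5) {
    n_rec <- sample(10:60, 1)
    rec <- tibble::tibble(
      region = sample(c("A", "B", "C"), n_rec, replace = TRUE),
      age = sample(0:99, n_rec, replace = TRUE)
    )
    out <- aggregate_events(rec, c("A", "B", "C"), groups = age_group_labels())
    expect_equal(sum(out$events), n_rec)
  }
})

test_that("ages bin into the fixed ten-year vocabulary at the boundaries", {
  rec <- tibble::tibble(region = c("A", "A", "A", "A"), age = c(84, 85, 0, 4))
  out <- aggregate_events(rec, "A", groups = age_group_labels())
  expect_equal(out$events[out$group == "75-84"], 1L)
  expect_equal(out$events[out$group == "85up"], 1L)
  expect_equal(out$events[out$group == "0-4"], 2L)

  # age outside all requested groups errors
  expect_error(
    aggregate_events(
      tibble::tibble(region = "A", age = 10), "A",
      groups = c("0-4", "85up")
    ),
    "outside all requested groups"
  )
})

test_that("unknown unit IDs error in strict mode and drop with warning otherwise", {
  rec <- tibble::tibble(region = c("A", "X"))
  expect_error(aggregate_events(rec, regions = "A"), "X")
  expect_warning(
    out <- aggregate_events(rec, regions = "A", strict = FALSE),
    "X"
  )
  expect_equal(out$events, 1L)
})

test_that("table validation reports nulls, bad types, and duplicate keys", {
  tbl <- tibble::tibble(
    region = c("A", "A", "B", NA),
    population = c("100", "200", "abc", "50")
  )
  rep <- validate_population_table(tbl)
  expect_true("duplicate_key" %in% rep$violation)
  expect_true(any(rep$violation == "non_numeric" & rep$row == 3))
  expect_true(any(rep$violation == "null" & rep$row == 4))

  clean <- tibble::tibble(region = c("A", "B", "C"), population = c(1, 2, 3))
  expect_identical(nrow(validate_population_table(clean)), 0L)
})

test_that("assembly reshapes to the model rank in adjacency order, row-order-stably", {
  adj <- adjacency(c("B", "A"), list(2L, 1L)) # note order: B first
  ev <- tidyr::expand_grid(region = c("A", "B"), group = c("g1", "g2")) |>
    dplyr::mutate(events = c(1, 2, 3, 4))
  pp <- ev |>
    dplyr::mutate(population = c(10, 20, 30, 40), events = NULL)
  inp <- assemble_model_input(ev, pp, adj, "mcar")
  expect_equal(dim(inp$events), c(2, 2, 1))
  expect_equal(inp$events["B", "g1", 1], 3)
  expect_equal(inp$events["A", "g2", 1], 2)

  # permuting rows changes nothing
  perm <- sample(nrow(ev))
  inp2 <- assemble_model_input(ev[perm, ], pp[rev(seq_len(nrow(pp))), ], adj, "mcar")
  expect_identical(inp2$events, inp$events)
  expect_identical(inp2$pops, inp$pops)
})

test_that("time spacing must be exactly equal for the spatiotemporal model", {
  adj <- adjacency(c("A", "B"), list(2L, 1L))
  mk <- function(times) {
    tidyr::expand_grid(region = c("A", "B"), group = "g1", time = times) |>
      dplyr::mutate(events = 1)
  }
  pp <- function(times) {
    tidyr::expand_grid(region = c("A", "B"), group = "g1", time = times) |>
      dplyr::mutate(population = 100)
  }
  ok <- assemble_model_input(mk(2021:2023), pp(2021:2023), adj, "mstcar")
  expect_equal(ok$time_labels, 2021:2023)
  expect_error(
    assemble_model_input(mk(c(2019, 2020, 2023)), pp(c(2019, 2020, 2023)), adj, "mstcar"),
    "equal distance"
  )
})

test_that("missing event cells error unless zero-fill is requested", {
  adj <- adjacency(c("A", "B"), list(2L, 1L))
  ev <- tibble::tibble(region = "A", events = 3)
  pp <- tibble::tibble(region = c("A", "B"), population = c(10, 20))
  expect_error(assemble_model_input(ev, pp, adj, "ucar"), "fill_zeros")
  inp <- assemble_model_input(ev, pp, adj, "ucar", fill_zeros = TRUE)
  expect_equal(inp$events["B", 1, 1], 0)
})

test_that("units absent from the adjacency are a key-mismatch error", {
  adj <- adjacency(c("A", "B"), list(2L, 1L))
  ev <- tibble::tibble(region = c("A", "B", "Z"), events = 1:3)
  pp <- tibble::tibble(region = c("A", "B", "Z"), population = c(10, 20, 30))
  expect_error(assemble_model_input(ev, pp, adj, "ucar"), "Z")
})

test_that("censored cells require a positive bound and keep their mask", {
  adj <- adjacency(c("A", "B"), list(2L, 1L))
  ev <- tibble::tibble(
    region = c("A", "B"), events = c(NA, 7),
    censored = c(TRUE, FALSE), censor_bound = c(10, NA)
  )
  pp <- tibble::tibble(region = c("A", "B"), population = c(100, 200))
  inp <- assemble_model_input(ev, pp, adj, "ucar")
  expect_true(inp$censored["A", 1, 1])
  expect_equal(inp$censor_bound["A", 1, 1], 10)

  ev_bad <- ev
  ev_bad$censor_bound <- c(-1, NA)
  expect_error(assemble_model_input(ev_bad, pp, adj, "ucar"), "positive censor_bound")
})

test_that("estimates tables round-trip through delimited files", {
  draws <- matrix(rexp(3 * 2000, 100), 3, 2000)
  est <- suppressWarnings(get_estimates(fake_samples(draws), ci_level = 0.95))
  est$suppressed[2] <- TRUE
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, path)
  back <- read_estimates(path)
  expect_equal(nrow(back), 3)
  for (cn in c("estimate", "lower", "upper", "relative_precision")) {
    expect_equal(signif(back[[cn]], 12), signif(est[[cn]], 12))
  }
  # suppression is a flag: the value is still present
  expect_true(back$suppressed[2])
  expect_false(is.na(back$estimate[2]))
})
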