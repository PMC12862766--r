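#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Internal constructor for the fitted-samples container.
new_rate_samples <- function(theta, model, input, config, hyper,
                             effects = NULL, imputed = NULL, acceptance) {
  events_obs <- input$events
  events_obs[input$censored] <- NA_real_
  structure(
    list(
      theta = theta,
      model = model,
      likelihood = config$likelihood,
      region_ids = input$adjacency$region_ids,
      group_labels = input$group_labels,
      time_labels = input$time_labels,
      events = events_obs,
      pops = input$pops,
      censored = input$censored,
      censor_bound = input$censor_bound,
      config = config,
      hyper = hyper,
      effects = effects,
      imputed = imputed,
      acceptance = acceptance
    ),
    class = "rate_samples"
  )
}

#' @export
print.rate_samples <- function(x, ...) {
  d <- dim(x$theta)
  cat(
    "<rate_samples> ", toupper(x$model), " (", x$likelihood, "): ",
    d[1], " regions x ", d[2], " groups x ", d[3], " periods, ",
    d[4], " saved draws\n",
    "  acceptance: ",
    paste(names(x$acceptance), round(x$acceptance, 3), sep = "=", collapse = " "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of saved posterior draws
#' @param samples A `rate_samples` object.
#' @return Integer draw count.
#' @export
n_draws <- function(samples) dim(samples$theta)[4]

# Long cell index in canonical (region fastest) order.
cell_table <- function(samples) {
  d <- dim(samples$theta)
  tibble::tibble(
    region = rep(samples$region_ids, times = d[2] * d[3]),
    group = rep(rep(as.character(samples$group_labels), each = d[1]), times = d[3]),
    time = rep(as.character(samples$time_labels), each = d[1] * d[2]),
    events = as.vector(samples$events),
    population = as.vector(samples$pops),
    censored = as.vector(samples$censored)
  )
}

# Draws as a cells x S matrix aligned with cell_table() rows.
cell_draws <- function(samples) {
  d <- dim(samples$theta)
  matrix(samples$theta, d[1] * d[2] * d[3], d[4])
}

#' @method glance rate_samples
#' @export
glance.rate_samples <- function(x, ...) {
  d <- dim(x$theta)
  tibble::tibble(
    model = x$model,
    likelihood = x$likelihood,
    regions = d[1],
    groups = d[2],
    periods = d[3],
    draws = d[4],
    iterations = x$config$iterations,
    burn_in = x$config$burn_in,
    thin = x$config$thin,
    censored_cells = sum(x$censored),
    accept_z = unname(x$acceptance["z"]),
    accept_eps = unname(x$acceptance["eps"]),
    accept_beta = unname(x$acceptance["beta"])
  )
}

#' @method tidy rate_samples
#' @export
tidy.rate_samples <- function(x, ci_level = 0.95, multiplier = 1, ...) {
  get_estimates(x, ci_level = ci_level, multiplier = multiplier)
}

#' Impute privacy-censored counts at given rates
#'
#' Draws each censored cell's count from its likelihood at the current
#' rate, truncated to the known range `[0, censor_bound - 1]`. This is the
#' update the samplers apply once per sweep; it is exposed for testing and
#' for custom samplers.
#'
#' @param theta Current rate(s), one per censored cell.
#' @param population Population denominator(s), recycled as needed.
#' @param censor_bound Strict upper bound(s); imputed counts lie in
#'   `[0, censor_bound - 1]`. Must be positive.
#' @param likelihood `"binomial"` or `"poisson"`.
#' @return Integer-valued draws, one per cell.
#' @export
impute_censored_step <- function(theta, population, censor_bound,
                                 likelihood = c("binomial", "poisson")) {
  likelihood <- match.arg(likelihood)
  if (any(censor_bound <= 0)) stop("censor_bound must be positive", call. = FALSE)
  rtrunc_count(theta, population, censor_bound, likelihood)
}

# ---- persistence -----------------------------------------------------------

#' Save / load posterior samples
#'
#' Self-describing plain-text container: a directory holding `meta.json`
#' (model, labels, configuration echo, acceptance rates), `theta.csv`
#' (long draws: region, group, time, draw, value), `cells.csv` (observed
#' events, populations, censoring), and optionally `imputed.csv` and
#' `hyper.csv`. `read_samples(write_samples(x, d))` reproduces the draws,
#' configuration, and data echoes exactly; identical fits write
#' byte-identical files.
#'
#' @param samples A `rate_samples` object.
#' @param dir Directory to create/fill.
#' @return `dir` invisibly (write); a `rate_samples` object (read).
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- samples$config
  meta <- list(
    model = samples$model,
    likelihood = samples$likelihood,
    region_ids = samples$region_ids,
    group_labels = as.character(samples$group_labels),
    time_labels = samples$time_labels,
    acceptance = as.list(samples$acceptance),
    config = cfg[setdiff(names(cfg), c("wishart_scale"))],
    wishart_scale = if (is.null(cfg$wishart_scale)) NULL else as.vector(cfg$wishart_scale)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  ct <- cell_table(samples)
  ct$censor_bound <- as.vector(samples$censor_bound)
  readr::write_csv(ct, file.path(dir, "cells.csv"), progress = FALSE)
  d <- dim(samples$theta)
  draws_long <- tibble::tibble(
    cell = rep(seq_len(d[1] * d[2] * d[3]), times = d[4]),
    draw = rep(seq_len(d[4]), each = d[1] * d[2] * d[3]),
    value = as.vector(samples$theta)
  )
  readr::write_csv(draws_long, file.path(dir, "theta.csv"), progress = FALSE)
  if (!is.null(samples$imputed)) {
    imp <- tibble::tibble(
      cell = rep(rownames(samples$imputed), times = ncol(samples$imputed)),
      draw = rep(seq_len(ncol(samples$imputed)), each = nrow(samples$imputed)),
      value = as.vector(samples$imputed)
    )
    readr::write_csv(imp, file.path(dir, "imputed.csv"), progress = FALSE)
  }
  if (!is.null(samples$hyper)) {
    readr::write_csv(samples$hyper, file.path(dir, "hyper.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_samples
#' @export
read_samples <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- meta$config
  config <- model_config(
    likelihood = cfg$likelihood, iterations = cfg$iterations,
    burn_in = cfg$burn_in, thin = cfg$thin, seed = cfg$seed,
    intercept_sd = cfg$intercept_sd, variance_shape = cfg$variance_shape,
    variance_rate = cfg$variance_rate,
    wishart_df = if (is.null(cfg$wishart_df)) NULL else cfg$wishart_df,
    wishart_scale = if (is.null(meta$wishart_scale)) NULL else meta$wishart_scale,
    rho_grid = cfg$rho_grid, ar_grid = cfg$ar_grid,
    adapt_target = cfg$adapt_target, pin_effects = isTRUE(cfg$pin_effects),
    rate_gamma_prior = if (is.null(cfg$rate_gamma_prior)) NULL else cfg$rate_gamma_prior,
    save_effects = isTRUE(cfg$save_effects)
  )
  cells <- readr::read_csv(file.path(dir, "cells.csv"),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      region = readr::col_character(), group = readr::col_character(),
      time = readr::col_character(), censored = readr::col_logical(),
      .default = readr::col_double()
    )
  )
  regions <- meta$region_ids
  groups <- meta$group_labels
  times <- meta$time_labels
  n <- length(regions)
  G <- length(groups)
  Tt <- length(times)
  draws <- readr::read_csv(file.path(dir, "theta.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  S <- max(draws$draw)
  theta <- array(NA_real_, c(n, G, Tt, S))
  theta[cbind(
    ((draws$cell - 1) %% n) + 1,
    (((draws$cell - 1) %/% n) %% G) + 1,
    ((draws$cell - 1) %/% (n * G)) + 1,
    draws$draw
  )] <- draws$value
  shape <- function(v) array(v, c(n, G, Tt), dimnames = list(regions, groups, as.character(times)))
  imputed <- NULL
  imp_path <- file.path(dir, "imputed.csv")
  if (file.exists(imp_path)) {
    imp <- readr::read_csv(imp_path,
      show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(cell = readr::col_character(), .default = readr::col_double())
    )
    cells_u <- unique(imp$cell)
    imputed <- matrix(imp$value, length(cells_u), max(imp$draw),
      dimnames = list(cells_u, NULL)
    )
  }
  hyper <- NULL
  if (file.exists(file.path(dir, "hyper.csv"))) {
    hyper <- readr::read_csv(file.path(dir, "hyper.csv"),
      show_col_types = FALSE, progress = FALSE
    )
  }
  structure(
    list(
      theta = theta,
      model = meta$model,
      likelihood = meta$likelihood,
      region_ids = regions,
      group_labels = groups,
      time_labels = times,
      events = shape(cells$events),
      pops = shape(cells$population),
      censored = shape(cells$censored),
      censor_bound = shape(cells$censor_bound),
      config = config,
      hyper = hyper,
      effects = NULL,
      imputed = imputed,
      acceptance = unlist(meta$acceptance)
    ),
    class = "rate_samples"
  )
}
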