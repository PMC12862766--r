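default_reliability_grid <- function() c(seq(0.50, 0.95, by = 0.05), 0.99)

#' Relative precision of an estimate
#'
#' The ratio of the posterior median to the width of its credible
#' interval. Estimates with relative precision strictly greater than 1
#' are deemed "reliable"; a ratio of exactly 1 is not reliable. The ratio
#' is scale-invariant: multiplying estimate and bounds by the same
#' positive constant leaves it unchanged. A zero-width interval (a
#' degenerate posterior) returns `+Inf` -- maximally precise by
#' convention.
#'
#' @param estimate Posterior median(s).
#' @param lower,upper Credible-interval bounds (`upper >= lower`).
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' relative_precision(2.0, 1.2, 2.8) # 1.25: reliable
#' relative_precision(1.0, 0.5, 1.5) # 1.00: NOT reliable (strict)
relative_precision <- function(estimate, lower, upper) {
  if (any(upper < lower, na.rm = TRUE)) {
    stop("upper credible bound below lower bound", call. = FALSE)
  }
  width <- upper - lower
  ifelse(width == 0, Inf, estimate / width)
}

# Vectorized over a cells x draws matrix: the largest grid level at which
# median / CI-width exceeds 1, NA if none.
lor_matrix <- function(draw_mat, level_grid) {
  if (length(level_grid) == 0) stop("empty reliability level grid", call. = FALSE)
  if (any(level_grid <= 0 | level_grid >= 1)) {
    stop("reliability levels must lie in (0, 1)", call. = FALSE)
  }
  level_grid <- sort(level_grid)
  med <- apply(draw_mat, 1, stats::median)
  out <- rep(NA_real_, nrow(draw_mat))
  for (lv in level_grid) {
    q <- apply(draw_mat, 1, stats::quantile, probs = c((1 - lv) / 2, (1 + lv) / 2), names = FALSE)
    rp <- relative_precision(med, q[1, ], q[2, ])
    out[rp > 1] <- lv # grid ascends, so the last passing level wins
  }
  out
}

#' Maximum credible level at which a draw set is reliable
#'
#' Searches a grid of credible levels for the largest one at which the
#' relative precision (median over CI width) still exceeds 1 -- the
#' estimate's "level of reliability". Reliability is monotone in the
#' level: reliable at some level implies reliable at every smaller one,
#' because interval width is non-decreasing in the level.
#'
#' @param draws Numeric vector of posterior draws for one cell.
#' @param level_grid Candidate levels in (0, 1), default
#'   `{0.50, 0.55, ..., 0.95, 0.99}`.
#' @return The maximum passing level, or `NA` if unreliable at every
#'   grid level.
#' @export
level_of_reliability <- function(draws, level_grid = default_reliability_grid()) {
  lor_matrix(matrix(draws, nrow = 1), level_grid)[1]
}

#' Extract an estimates table from posterior samples
#'
#' One row per (region, group, time) cell: the posterior median as the
#' estimate, credible bounds as the `(1-a)/2` and `(1+a)/2` sample
#' quantiles (linear-interpolation type-7 quantiles), relative precision,
#' the strict `> 1` reliability flag, and the level of reliability over a
#' grid of credible levels. All quantities are scaled by `multiplier`
#' (default rates per 100,000). The `suppressed` column starts `FALSE`;
#' see [apply_suppression()].
#'
#' @param samples A `rate_samples` object.
#' @param ci_level Credible level `a` in (0, 1), default 0.95.
#' @param multiplier Rate scale, default `1e5`.
#' @param reliability_grid Grid for [level_of_reliability()].
#' @return A tibble (class `rate_estimates`) with columns `region`,
#'   `group`, `time`, `events`, `population`, `estimate`, `lower`,
#'   `upper`, `ci_level`, `relative_precision`, `reliable`,
#'   `level_of_reliability`, `suppressed`.
#' @export
get_estimates <- function(samples, ci_level = 0.95, multiplier = 1e5,
                          reliability_grid = default_reliability_grid()) {
  stopifnot(inherits(samples, "rate_samples"))
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must lie in (0, 1)", call. = FALSE)
  dm <- cell_draws(samples)
  if (ncol(dm) < 1000) {
    warning("only ", ncol(dm), " saved draws; quantile estimates may be noisy", call. = FALSE)
  }
  med <- apply(dm, 1, stats::median)
  q <- apply(dm, 1, stats::quantile,
    probs = c((1 - ci_level) / 2, (1 + ci_level) / 2), names = FALSE
  )
  rp <- relative_precision(med, q[1, ], q[2, ])
  out <- cell_table(samples) |>
    dplyr::mutate(
      estimate = med * multiplier,
      lower = q[1, ] * multiplier,
      upper = q[2, ] * multiplier,
      ci_level = ci_level,
      relative_precision = rp,
      reliable = rp > 1,
      level_of_reliability = lor_matrix(dm, reliability_grid),
      suppressed = FALSE
    ) |>
    dplyr::select(-"censored")
  class(out) <- c("rate_estimates", class(out))
  attr(out, "multiplier") <- multiplier
  out
}

#' Direct age-standardization of posterior samples
#'
#' Collapses the group axis by a weighted average of group-specific rates
#' using a standard population's weights, applied draw by draw so that
#' downstream credible intervals reflect the standardization. Weights are
#' renormalized over the groups present in the samples.
#'
#' @param samples A `rate_samples` object with a group axis.
#' @param std A standard population: tibble with `group` and `weight`
#'   columns, e.g. from [standard_population()].
#' @return A `rate_samples` object with a single group `"std"`; events
#'   and populations are summed over the original groups.
#' @export
age_standardize <- function(samples, std = standard_population("2010")) {
  stopifnot(inherits(samples, "rate_samples"))
  std <- tibble::as_tibble(std)
  groups <- as.character(samples$group_labels)
  w <- std$weight[match(groups, std$group)]
  if (anyNA(w)) {
    stop(
      "group(s) absent from the standard population: ",
      paste(groups[is.na(w)], collapse = ", "),
      call. = FALSE
    )
  }
  if (any(w <= 0)) stop("standard-population weights must be positive", call. = FALSE)
  w <- w / sum(w)
  collapse_groups(samples, weights_array = NULL, fixed_weights = w, label = "std")
}

#' Aggregate posterior samples across groups
#'
#' Merges group labels draw-wise with population weights: the merged rate
#' in a draw is `sum(n_g * theta_g) / sum(n_g)` over the merged labels,
#' using each cell's own population. Use this, for example, to aggregate
#' across sexes before age-standardizing across age bands.
#'
#' @param samples A `rate_samples` object.
#' @param mapping Named list partitioning the group labels, e.g.
#'   `list(adult = c("25-34", "35-44"))`; default merges all groups into
#'   `"all"`.
#' @return A `rate_samples` object on the merged labels.
#' @export
aggregate_groups <- function(samples, mapping = NULL) {
  stopifnot(inherits(samples, "rate_samples"))
  groups <- as.character(samples$group_labels)
  if (is.null(mapping)) mapping <- list(all = groups)
  flat <- unlist(mapping, use.names = FALSE)
  if (!setequal(flat, groups) || anyDuplicated(flat)) {
    stop("mapping must partition the group labels exactly", call. = FALSE)
  }
  pieces <- lapply(names(mapping), function(lbl) {
    collapse_groups(
      subset_groups(samples, mapping[[lbl]]),
      weights_array = TRUE, fixed_weights = NULL, label = lbl
    )
  })
  out <- pieces[[1]]
  if (length(pieces) > 1) {
    out$theta <- do.call(abind4_g, lapply(pieces, function(p) p$theta))
    out$events <- abind3_g(lapply(pieces, function(p) p$events))
    out$pops <- abind3_g(lapply(pieces, function(p) p$pops))
    out$censored <- abind3_g(lapply(pieces, function(p) p$censored))
    out$censor_bound <- abind3_g(lapply(pieces, function(p) p$censor_bound))
    out$group_labels <- names(mapping)
  }
  out
}

subset_groups <- function(samples, keep) {
  idx <- match(keep, as.character(samples$group_labels))
  s <- samples
  s$theta <- samples$theta[, idx, , , drop = FALSE]
  s$events <- samples$events[, idx, , drop = FALSE]
  s$pops <- samples$pops[, idx, , drop = FALSE]
  s$censored <- samples$censored[, idx, , drop = FALSE]
  s$censor_bound <- samples$censor_bound[, idx, , drop = FALSE]
  s$group_labels <- keep
  s
}

abind4_g <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(d[1], length(arrs), d[3], d[4]))
  for (g in seq_along(arrs)) out[, g, , ] <- arrs[[g]]
  out
}

abind3_g <- function(arrs) {
  d <- dim(arrs[[1]])
  out <- array(arrs[[1]][1][NA], c(d[1], length(arrs), d[3]))
  for (g in seq_along(arrs)) out[, g, ] <- arrs[[g]]
  out
}

# Collapse the group axis of a rate_samples object, either with fixed
# weights (standardization) or each cell's population shares (aggregation).
collapse_groups <- function(samples, weights_array, fixed_weights, label) {
  d <- dim(samples$theta)
  n <- d[1]
  G <- d[2]
  Tt <- d[3]
  S <- d[4]
  num <- array(0, c(n, Tt, S))
  if (is.null(fixed_weights)) {
    den <- array(0, c(n, Tt))
    for (g in seq_len(G)) {
      ng <- matrix(samples$pops[, g, ], n, Tt)
      num <- num + array(samples$theta[, g, , ], c(n, Tt, S)) * as.vector(ng)
      den <- den + ng
    }
    if (any(den == 0)) stop("zero total population in a merged group", call. = FALSE)
    num <- num / as.vector(den)
  } else {
    for (g in seq_len(G)) {
      num <- num + fixed_weights[g] * array(samples$theta[, g, , ], c(n, Tt, S))
    }
  }
  s <- samples
  s$theta <- array(num, c(n, 1, Tt, S))
  sum_g <- function(A) array(apply(A, c(1, 3), sum), c(n, 1, Tt))
  s$events <- sum_g(samples$events)
  s$pops <- sum_g(samples$pops)
  cz <- apply(samples$censored, c(1, 3), any)
  s$censored <- array(cz, c(n, 1, Tt))
  s$censor_bound <- array(NA_real_, c(n, 1, Tt))
  s$group_labels <- label
  s$effects <- NULL
  s$imputed <- NULL
  s
}

#' Flag rows for suppression
#'
#' Applies display-suppression rules as flags, never deleting values.
#' For model-based tables (with a `reliable` column) a row is suppressed
#' when it is not reliable at the table's credible level or its population
#' falls below `pop_threshold`. For crude (unmodeled) tables, pass
#' `event_rule`: a row is suppressed when its event count is below that
#' minimum (for example the 16-event rule used for unsmoothed death
#' rates).
#'
#' @param table An estimates tibble from [get_estimates()], or a crude
#'   table from [crude_rates()] when `event_rule` is given.
#' @param pop_threshold Minimum population to display (default 100;
#'   common choices are 30 or 100).
#' @param event_rule Optional minimum event count, crude tables only.
#' @return The table with its `suppressed` column set.
#' @export
apply_suppression <- function(table, pop_threshold = 100, event_rule = NULL) {
  if (!is.null(event_rule)) {
    table$suppressed <- !is.na(table$events) & table$events < event_rule |
      is.na(table$events)
    return(table)
  }
  if (!"reliable" %in% names(table)) {
    stop("model-based suppression needs a 'reliable' column; for crude tables pass event_rule", call. = FALSE)
  }
  table$suppressed <- !table$reliable | table$population < pop_threshold
  table
}

#' Compare estimates to a reference rate
#'
#' Classifies each cell against a reference value using its credible
#' interval: `"higher"` when the lower bound exceeds the reference,
#' `"lower"` when the upper bound is below it, `"not_different"`
#' otherwise. Unreliable estimates can still be significantly different.
#' Given posterior samples, also returns the exceedance probability (the
#' fraction of draws strictly above the reference).
#'
#' @param x A `rate_samples` object, or an estimates table with `lower`
#'   and `upper` columns already on the reference's scale.
#' @param reference Reference rate on the scale implied by `multiplier`.
#' @param ci_level Credible level for the comparison interval.
#' @param multiplier Rate scale applied to the draws (samples method).
#' @param ... Passed between methods.
#' @return A tibble with labels, bounds, `classification`, and (samples
#'   method) `exceedance_probability`.
#' @export
compare_to_reference <- function(x, reference, ...) {
  UseMethod("compare_to_reference")
}

#' @rdname compare_to_reference
#' @export
compare_to_reference.rate_samples <- function(x, reference, ci_level = 0.95,
                                              multiplier = 1e5, ...) {
  est <- get_estimates(x, ci_level = ci_level, multiplier = multiplier)
  dm <- cell_draws(x) * multiplier
  est |>
    dplyr::transmute(
      .data$region, .data$group, .data$time,
      .data$estimate, .data$lower, .data$upper,
      classification = classify_ci(.data$lower, .data$upper, reference),
      exceedance_probability = rowMeans(dm > reference)
    )
}

#' @rdname compare_to_reference
#' @export
compare_to_reference.data.frame <- function(x, reference, ...) {
  x |>
    dplyr::mutate(classification = classify_ci(.data$lower, .data$upper, reference))
}

classify_ci <- function(lower, upper, reference) {
  dplyr::case_when(
    lower > reference ~ "higher",
    upper < reference ~ "lower",
    TRUE ~ "not_different"
  )
}

#' Exceedance probability
#'
#' The fraction of posterior draws strictly greater than a reference
#' value, so that `P(> v) = 1 - P(<= v)` exactly; ties count as not
#' exceeding.
#'
#' @param x A numeric vector of draws, or a `rate_samples` object.
#' @param reference Reference value (on the draw scale, or the
#'   `multiplier` scale for the samples method).
#' @param multiplier Rate scale (samples method only).
#' @param ... Passed between methods.
#' @return A probability (vector method) or a per-cell tibble.
#' @export
exceedance_probability <- function(x, reference, ...) {
  UseMethod("exceedance_probability")
}

#' @rdname exceedance_probability
#' @export
exceedance_probability.numeric <- function(x, reference, ...) {
  if (length(x) < 1) stop("need at least one draw", call. = FALSE)
  mean(x > reference)
}

#' @rdname exceedance_probability
#' @export
exceedance_probability.rate_samples <- function(x, reference, multiplier = 1e5, ...) {
  dm <- cell_draws(x) * multiplier
  cell_table(x) |>
    dplyr::transmute(
      .data$region, .data$group, .data$time,
      exceedance_probability = rowMeans(dm > reference)
    )
}

#' Crude (unmodeled) rates
#'
#' Event counts divided by population sizes, the comparison baseline for
#' the smoothed estimates. Cells with zero population and a positive
#' count are an error; zero-population zero-count cells get an undefined
#' (NA) rate and are flagged.
#'
#' @param input A `model_input`.
#' @param multiplier Rate scale, default per 100,000.
#' @return Tibble: `region`, `group`, `time`, `events`, `population`,
#'   `rate`, `undefined`, `suppressed` (initialized `FALSE`).
#' @export
crude_rates <- function(input, multiplier = 1e5) {
  stopifnot(inherits(input, "model_input"))
  d <- dim(input$events)
  ev <- input$events
  ev[input$censored] <- NA_real_
  out <- tibble::tibble(
    region = rep(input$adjacency$region_ids, times = d[2] * d[3]),
    group = rep(rep(as.character(input$group_labels), each = d[1]), times = d[3]),
    time = rep(as.character(input$time_labels), each = d[1] * d[2]),
    events = as.vector(ev),
    population = as.vector(input$pops)
  )
  bad <- !is.na(out$events) & out$population == 0 & out$events > 0
  if (any(bad)) {
    stop(
      "positive event count with zero population in: ",
      paste(out$region[bad], collapse = ", "),
      call. = FALSE
    )
  }
  out |>
    dplyr::mutate(
      undefined = .data$population == 0,
      rate = dplyr::if_else(.data$undefined, NA_real_, .data$events / .data$population * multiplier),
      suppressed = FALSE
    )
}
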