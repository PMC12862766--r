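#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' Caterpillar plot of an estimates table
#'
#' Cells ordered by estimate, with credible-interval whiskers; suppressed
#' cells are greyed out, unreliable ones hollow.
#'
#' @param object A `rate_estimates` tibble from [get_estimates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rate_estimates
#' @export
autoplot.rate_estimates <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    cell = paste(.data$region, .data$group, .data$time, sep = "|"),
    status = dplyr::case_when(
      .data$suppressed ~ "suppressed",
      !.data$reliable ~ "unreliable",
      TRUE ~ "reliable"
    )
  )
  df$cell <- stats::reorder(df$cell, df$estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$estimate)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper, colour = .data$status),
      alpha = 0.6
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status, shape = .data$status), size = 0.9) +
    ggplot2::scale_colour_manual(values = c(
      reliable = "#1b6ca8", unreliable = "#c77d2e", suppressed = "grey60"
    )) +
    ggplot2::scale_shape_manual(values = c(reliable = 16, unreliable = 1, suppressed = 4)) +
    ggplot2::labs(
      x = NULL, y = paste0("rate per ", format(attr(object, "multiplier") %||% 1e5, big.mark = ",")),
      colour = NULL, shape = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Bar chart of levels of reliability
#'
#' Shows how many cells reach each maximum credible level at which their
#' relative precision exceeds 1 -- the map-legend view of estimate
#' quality.
#'
#' @param estimates A `rate_estimates` tibble.
#' @return A ggplot object.
#' @export
plot_reliability <- function(estimates) {
  df <- estimates |>
    dplyr::mutate(
      level = factor(
        ifelse(is.na(.data$level_of_reliability), "none",
          format(.data$level_of_reliability)
        )
      )
    ) |>
    dplyr::count(.data$level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$n)) +
    ggplot2::geom_col(fill = "#1b6ca8") +
    ggplot2::labs(x = "level of reliability (max credible level with RP > 1)", y = "cells") +
    ggplot2::theme_minimal()
}

#' Smoothed-versus-crude shrinkage plot
#'
#' Plots crude rates against smoothed estimates with the identity line;
#' point size tracks population, making the shrinkage of small-population
#' cells toward their neighbors visible.
#'
#' @param estimates A `rate_estimates` tibble.
#' @param crude A crude-rates tibble from [crude_rates()] on the same
#'   cells and scale.
#' @return A ggplot object.
#' @export
plot_shrinkage <- function(estimates, crude) {
  df <- dplyr::inner_join(
    dplyr::select(estimates, "region", "group", "time", "estimate", "population"),
    dplyr::select(crude, "region", "group", "time", crude_rate = "rate"),
    by = c("region", "group", "time")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$crude_rate, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$population), alpha = 0.5, colour = "#1b6ca8") +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::labs(x = "crude rate", y = "smoothed estimate", size = "population") +
    ggplot2::theme_minimal()
}
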