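#' US Standard Population weights in 10-year age bands
#'
#' Standard-population weights for direct age-standardization, in the
#' ten-year age-band vocabulary of [age_group_labels()]. The `"2000"`
#' vintage uses the year-2000 US standard population counts (in
#' thousands) as disseminated with federal cancer statistics; the
#' `"2010"` vintage uses 2010 decennial census resident-population counts
#' aggregated to the same bands. These are external constants supplied
#' for convenience; for a custom standard, pass any tibble with `group`
#' and `weight` columns to [age_standardize()] instead.
#'
#' Weights are renormalized to sum to 1 over the requested labels, so a
#' standardization restricted to a subset of bands (say ages 35 and up)
#' uses the proper conditional weights.
#'
#' @param vintage `"2000"` or `"2010"`.
#' @param labels Age-band labels to include (default: all ten).
#' @return Tibble with columns `group` and `weight` (summing to 1).
#' @export
#' @examples
#' standard_population("2000", labels = c("35-44", "45-54", "55-64"))
standard_population <- function(vintage = c("2010", "2000"),
                                labels = age_group_labels()) {
  vintage <- as.character(vintage)
  vintage <- match.arg(vintage)
  counts <- switch(vintage,
    "2000" = c(
      "0-4" = 18987, "5-14" = 39977, "15-24" = 38077, "25-34" = 37233,
      "35-44" = 44659, "45-54" = 37030, "55-64" = 23961, "65-74" = 18136,
      "75-84" = 12315, "85up" = 4259
    ),
    "2010" = c(
      "0-4" = 20201362, "5-14" = 41025851, "15-24" = 43626342,
      "25-34" = 41063948, "35-44" = 41070606, "45-54" = 45006716,
      "55-64" = 36482729, "65-74" = 21713429, "75-84" = 13061122,
      "85up" = 5493433
    )
  )
  labels <- age_group_bounds(labels)$group # validates + orders
  w <- counts[labels]
  tibble::tibble(group = labels, weight = as.numeric(w / sum(w)))
}
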