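#' Stressor summaries by population-density category
#'
#' Descriptive statistics (mean, sd, median, min, max) of all daily
#' area-level values, split by the four population-density categories.
#' Daily values are pooled, not averaged per area first, so min/max are
#' daily extremes.
#'
#' @param panel A stressor panel tibble.
#' @param areas The matching `area_set` (supplies population and area).
#' @return A tibble with one row per variable and category: `variable`,
#'   `category`, `n_areas`, `n_obs`, `mean`, `sd`, `median`, `min`,
#'   `max`.
#' @export
density_strata_summary <- function(panel, areas) {
  check_panel(panel)
  check_area_set(areas)
  cats <- tibble(
    area_id = areas$id,
    category = categorize_density(
      population_density(areas$population, areas$area_km2)
    )
  )
  panel |>
    dplyr::inner_join(cats, by = "area_id") |>
    dplyr::group_by(.data$variable, .data$category) |>
    dplyr::summarise(
      n_areas = dplyr::n_distinct(.data$area_id),
      n_obs = dplyr::n(),
      mean = mean(.data$value), sd = sd(.data$value),
      median = median(.data$value),
      min = min(.data$value), max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$variable, .data$category)
}

#' Stressor summaries by LISA stratum
#'
#' Splits the areas into the four LISA strata -- hot spots (`HH`), cold
#' spots (`LL`), isolated areas (no neighbors) and everything else
#' (non-significant, including the discordant `HL`/`LH` outliers) --
#' and summarizes all daily area-level values of `variable` within each
#' stratum. Empty strata are reported with `n_obs = 0` and `NA`
#' statistics.
#'
#' @param panel A stressor panel tibble.
#' @param lisa A `lisa_result` for `variable` (see [lisa_hotspots()]).
#' @param variable Variable to summarize.
#' @return A tibble with one row per stratum: `stratum`, `n_areas`,
#'   `n_obs`, `mean`, `sd`, `median`, `min`, `max`.
#' @export
lisa_strata_summary <- function(panel, lisa, variable) {
  check_panel(panel)
  if (!variable %in% panel$variable) {
    stop_key(sprintf("variable `%s` is not present in the panel.", variable))
  }
  strata_levels <- c("hot", "cold", "isolated", "non-significant")
  strata <- tibble(
    area_id = lisa$area_id,
    stratum = factor(dplyr::case_when(
      lisa$island ~ "isolated",
      lisa$label == "HH" ~ "hot",
      lisa$label == "LL" ~ "cold",
      TRUE ~ "non-significant"
    ), levels = strata_levels)
  )
  stats <- panel |>
    dplyr::filter(.data$variable == !!variable) |>
    dplyr::inner_join(strata, by = "area_id") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_areas = dplyr::n_distinct(.data$area_id),
      n_obs = dplyr::n(),
      mean = mean(.data$value), sd = sd(.data$value),
      median = median(.data$value),
      min = min(.data$value), max = max(.data$value),
      .groups = "drop"
    )
  tibble(stratum = factor(strata_levels, levels = strata_levels)) |>
    dplyr::left_join(stats, by = "stratum") |>
    dplyr::mutate(
      n_areas = dplyr::coalesce(.data$n_areas, 0L),
      n_obs = dplyr::coalesce(.data$n_obs, 0L)
    )
}
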