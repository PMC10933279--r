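#' Read an area set from a GeoJSON FeatureCollection
#'
#' Expects planar polygon features with properties `id` and `population`
#' (required) and `area_km2` (computed from the ring by the shoelace
#' formula when absent). Duplicate ids and degenerate rings are
#' rejected.
#'
#' @param path Path to a GeoJSON file.
#' @return An `area_set` tibble (see [make_lattice()] for the columns;
#'   `row`/`col` are present only for lattice-generated files).
#' @export
read_areas <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop_schema("expected a GeoJSON FeatureCollection.")
  }
  feats <- gj$features
  if (!length(feats)) stop_schema("FeatureCollection has no features.")

  rows <- lapply(seq_along(feats), function(k) {
    f <- feats[[k]]
    props <- f$properties
    id <- props$id
    if (is.null(id)) {
      stop_schema(sprintf("feature %d has no `id` property.", k))
    }
    if (is.null(props$population)) {
      stop_schema(sprintf("feature with id `%s` has no `population` property.", id))
    }
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      abort(sprintf("feature `%s` is not a Polygon.", id),
            class = "stressorscape_geometry_error")
    }
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], unlist))
    if (nrow(ring) < 4 ||
        any(ring[1, ] != ring[nrow(ring), ]) ||
        ring_area(ring) <= 0) {
      abort(sprintf("feature `%s` has an invalid ring.", id),
            class = "stressorscape_geometry_error")
    }
    colnames(ring) <- c("x", "y")
    area <- props$area_km2 %||% ring_area(ring)
    list(id = as.character(id), area_km2 = as.numeric(area),
         population = as.numeric(props$population), geometry = ring)
  })

  ids <- vapply(rows, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate area ids: %s", paste(dup, collapse = ", ")),
          class = "stressorscape_duplicate_id_error")
  }
  geometry <- lapply(rows, `[[`, "geometry")
  centers <- vapply(geometry, function(r) colMeans(r[-nrow(r), , drop = FALSE]),
                    numeric(2))
  out <- tibble(
    id = ids,
    x = centers[1, ], y = centers[2, ],
    area_km2 = vapply(rows, `[[`, numeric(1), "area_km2"),
    population = vapply(rows, `[[`, numeric(1), "population"),
    geometry = geometry
  )
  class(out) <- c("area_set", class(out))
  out
}

#' Read / write a long-format stressor panel CSV
#'
#' The canonical on-disk panel format is a CSV with header
#' `area_id,date,variable,value` and ISO-8601 dates.
#'
#' @param path File path.
#' @return `read_panel()` returns the panel tibble; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_panel(df, arg = path)
  df$date <- as.Date(df$date)
  as_tibble(df)
}

#' @rdname read_panel
#' @param panel A stressor panel tibble.
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  utils::write.csv(panel[, c("area_id", "date", "variable", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Population density of an area
#'
#' Inhabitants per square kilometre: `population / area_km2`.
#'
#' @param population Number of inhabitants (nonnegative).
#' @param area_km2 Area in km2 (strictly positive).
#' @return Density in inhabitants/km2 (vectorized).
#' @examples
#' population_density(630000, 207.3)
#' @export
population_density <- function(population, area_km2) {
  if (any(area_km2 <= 0)) stop_domain("`area_km2` must be positive.")
  if (any(population < 0)) stop_domain("`population` must be nonnegative.")
  population / area_km2
}

#' Population-density category
#'
#' Assigns the four density categories used for stratified summaries:
#' category 1 covers 0-150 inhabitants/km2, 2 covers 151-300, 3 covers
#' 301-1000 and 4 is above 1000. Bins are half-open on the left,
#' `(0,150], (150,300], (300,1000], (1000, Inf)`, so a density exactly
#' on a printed boundary falls in the lower category and fractional
#' densities just above it in the upper one.
#'
#' @param density Density in inhabitants/km2 (nonnegative, vectorized).
#' @return Integer category 1-4.
#' @examples
#' categorize_density(c(150, 150.5, 1000, 1000.01))
#' @export
categorize_density <- function(density) {
  if (any(density < 0)) stop_domain("`density` must be nonnegative.")
  1L + (density > 150) + (density > 300) + (density > 1000)
}

#' Vapor pressure from dewpoint temperature (Magnus formula)
#'
#' The Magnus/Bolton empirical form
#' `e = 6.112 * exp(17.67 * Td / (Td + 243.5))` giving water vapor
#' pressure in hPa from the dewpoint `Td` in deg C; strictly increasing
#' in `Td` and accurate to about 0.3% against tabulated saturation
#' vapor pressures over the meteorological range. `strict_literal`
#' switches the denominator to `Td - 243.5` for auditing sources that
#' print the formula with that (nonphysical) sign; its values are not
#' meaningful vapor pressures.
#'
#' @param dewpoint_C Dewpoint temperature in deg C, above -243.5.
#' @param strict_literal Use the `Td - 243.5` denominator as sometimes
#'   printed (default `FALSE`).
#' @return Vapor pressure in hPa (vectorized).
#' @examples
#' magnus_vapor_pressure(0)   # 6.112 exactly
#' magnus_vapor_pressure(20)
#' @export
magnus_vapor_pressure <- function(dewpoint_C, strict_literal = FALSE) {
  if (strict_literal) {
    if (any(dewpoint_C >= 243.5)) {
      stop_domain("literal form is singular at Td = 243.5 deg C.")
    }
    return(6.112 * exp(17.67 * dewpoint_C / (dewpoint_C - 243.5)))
  }
  if (any(dewpoint_C <= -243.5)) {
    stop_domain("`dewpoint_C` must exceed -243.5 deg C.")
  }
  6.112 * exp(17.67 * dewpoint_C / (dewpoint_C + 243.5))
}

#' Convert accumulated UV energy to mean power
#'
#' Divides an energy flux accumulated over an integration period
#' (J/m2) by the period length in seconds, giving W/m2.
#'
#' @param energy_J_per_m2 Accumulated energy in J/m2.
#' @param integration_seconds Length of the accumulation period in
#'   seconds (positive).
#' @return Mean irradiance in W/m2 (vectorized).
#' @export
uv_to_watts <- function(energy_J_per_m2, integration_seconds) {
  if (any(integration_seconds <= 0)) {
    stop_domain("`integration_seconds` must be positive.")
  }
  energy_J_per_m2 / integration_seconds
}

#' Aggregate a gridded raster to areas by area-weighted mean
#'
#' For every area and day, averages the raster cells intersecting the
#' polygon, weighted by the planar intersection area
#' (Sutherland-Hodgman polygon clipping against each rectangular cell).
#' Weights are computed once from the geometry and reused across days.
#'
#' @param raster A raster tibble as from [simulate_grid()]: columns
#'   `date`, `x`, `y` (cell centers), `value`, with the cell side length
#'   in attribute `cell_size` (or passed as `cell_size`).
#' @param areas An `area_set` tibble.
#' @param variable Variable name recorded in the output panel.
#' @param cell_size Cell side length; defaults to the raster attribute.
#' @return A stressor panel tibble (`area_id`, `date`, `variable`,
#'   `value`).
#' @export
aggregate_grid_to_areas <- function(raster, areas, variable = "value",
                                    cell_size = NULL) {
  check_area_set(areas)
  cell_size <- cell_size %||% attr(raster, "cell_size")
  if (is.null(cell_size)) {
    stop_schema("`cell_size` not given and not recorded on the raster.")
  }
  cells <- dplyr::distinct(raster[, c("x", "y")])
  w <- intersection_weights(areas, cells, cell_size)
  uncovered <- areas$id[rowSums(w) <= 0]
  if (length(uncovered)) {
    abort(
      sprintf("areas not covered by the raster: %s",
              paste(uncovered, collapse = ", ")),
      class = "stressorscape_coverage_error"
    )
  }
  w <- w / rowSums(w)

  key <- paste(cells$x, cells$y)
  out <- raster |>
    dplyr::group_by(.data$date) |>
    dplyr::group_modify(function(d, g) {
      vals <- d$value[match(key, paste(d$x, d$y))]
      tibble(area_id = areas$id, value = as.numeric(w %*% vals))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(variable = variable) |>
    dplyr::select("area_id", "date", "variable", "value")
  out
}

# Area-by-cell matrix of polygon/rectangle intersection areas.
intersection_weights <- function(areas, cells, cell_size) {
  half <- cell_size / 2
  n_a <- nrow(areas)
  n_c <- nrow(cells)
  w <- matrix(0, n_a, n_c)
  for (i in seq_len(n_a)) {
    ring <- areas$geometry[[i]]
    bx <- range(ring[, 1]); by <- range(ring[, 2])
    near <- which(cells$x + half > bx[1] & cells$x - half < bx[2] &
                    cells$y + half > by[1] & cells$y - half < by[2])
    for (j in near) {
      clipped <- clip_ring_to_rect(
        ring,
        cells$x[j] - half, cells$x[j] + half,
        cells$y[j] - half, cells$y[j] + half
      )
      if (!is.null(clipped) && nrow(clipped) >= 3) {
        w[i, j] <- ring_area(rbind(clipped, clipped[1, , drop = FALSE]))
      }
    }
  }
  w
}

# Sutherland-Hodgman clipping of an (open or closed) ring against an
# axis-aligned rectangle. Returns an open polygon matrix or NULL.
clip_ring_to_rect <- function(ring, xmin, xmax, ymin, ymax) {
  poly <- ring
  if (all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  edges <- list(
    function(p) p[1] >= xmin, function(p) p[1] <= xmax,
    function(p) p[2] >= ymin, function(p) p[2] <= ymax
  )
  inter <- list(
    function(a, b) { t <- (xmin - a[1]) / (b[1] - a[1]); a + t * (b - a) },
    function(a, b) { t <- (xmax - a[1]) / (b[1] - a[1]); a + t * (b - a) },
    function(a, b) { t <- (ymin - a[2]) / (b[2] - a[2]); a + t * (b - a) },
    function(a, b) { t <- (ymax - a[2]) / (b[2] - a[2]); a + t * (b - a) }
  )
  for (e in seq_along(edges)) {
    if (nrow(poly) == 0) return(NULL)
    inside <- edges[[e]]
    cross <- inter[[e]]
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(poly)
    for (k in seq_len(n)) {
      a <- poly[k, ]
      b <- poly[if (k == n) 1 else k + 1, ]
      ain <- inside(a); bin <- inside(b)
      if (ain && bin) {
        out <- rbind(out, b)
      } else if (ain && !bin) {
        out <- rbind(out, cross(a, b))
      } else if (!ain && bin) {
        out <- rbind(out, cross(a, b), b)
      }
    }
    poly <- out
  }
  if (nrow(poly) < 3) NULL else poly
}

#' Collapse an hourly panel to daily means
#'
#' Computes the arithmetic mean of available hours per area, calendar
#' day and variable. Days with fewer than `min_completeness` of
#' `hours_per_day` hours present are dropped (and counted in a
#' message). Day boundaries follow the timestamps' own clock; no
#' timezone shifting is applied.
#'
#' @param hourly A tibble with columns `area_id`, `timestamp`
#'   (POSIXct), `variable`, `value`.
#' @param min_completeness Minimum fraction of hours required to keep a
#'   day (default 0.75).
#' @param hours_per_day Nominal number of hourly records per day.
#' @return A daily stressor panel tibble.
#' @export
daily_mean <- function(hourly, min_completeness = 0.75, hours_per_day = 24) {
  if (!nrow(hourly)) {
    warn("empty hourly input; returning an empty panel.")
    return(tibble(area_id = character(), date = as.Date(character()),
                  variable = character(), value = numeric()))
  }
  need <- c("area_id", "timestamp", "variable", "value")
  if (!all(need %in% names(hourly))) {
    stop_schema("hourly input needs columns area_id, timestamp, variable, value.")
  }
  min_hours <- ceiling(min_completeness * hours_per_day)
  daily <- hourly |>
    dplyr::mutate(date = as.Date(format(.data$timestamp, "%Y-%m-%d"))) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$area_id, .data$date, .data$variable) |>
    dplyr::summarise(value = mean(.data$value), n_hours = dplyr::n(),
                     .groups = "drop")
  dropped <- sum(daily$n_hours < min_hours)
  if (dropped > 0) {
    message(sprintf("daily_mean: dropped %d incomplete area-day(s) (< %d hours).",
                    dropped, min_hours))
  }
  daily |>
    dplyr::filter(.data$n_hours >= min_hours) |>
    dplyr::select("area_id", "date", "variable", "value")
}
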