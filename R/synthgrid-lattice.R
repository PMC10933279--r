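#' Generate a synthetic lattice of administrative areas
#'
#' Builds an `nx` by `ny` grid of unit-square cells (1 km2 each by
#' convention) standing in for a set of postal-code polygons, and draws a
#' population for every cell so that all four population-density
#' categories (0-150, 151-300, 301-1000, >1000 inhabitants/km2) occur.
#' Rural background density is log-normal; one or more urban centers add
#' a Gaussian density bump whose core exceeds 1000 inhabitants/km2.
#'
#' @param nx,ny Lattice dimensions in cells; both must be at least 3.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param urban_centers List of urban centers, each a list with elements
#'   `x`, `y` (cell coordinates), `radius` (cells) and `intensity` (peak
#'   added density, inhabitants/km2). Defaults to a single center at the
#'   lattice midpoint.
#' @param cell_km Side length of a cell in km (default 1).
#'
#' @return A tibble of class `area_set` with one row per cell: `id`,
#'   `row`, `col`, `x`, `y` (cell center), `area_km2`, `population`, and
#'   a `geometry` list-column of closed polygon rings (5 x 2 matrices).
#' @examples
#' areas <- make_lattice(5, 5, seed = 1)
#' nrow(areas)
#' @export
make_lattice <- function(nx, ny, seed = 1L, urban_centers = NULL, cell_km = 1) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 3 || ny < 3) {
    abort("`nx` and `ny` must both be at least 3.",
          class = "stressorscape_dimension_error")
  }
  nx <- as.integer(nx)
  ny <- as.integer(ny)
  n <- nx * ny
  urban_centers <- urban_centers %||% default_urban_centers(nx, ny)

  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  cx <- (col - 0.5) * cell_km
  cy <- (row - 0.5) * cell_km

  width <- max(3L, nchar(as.character(n - 1L)))
  ids <- sprintf(paste0("A%0", width, "d"), seq_len(n) - 1L)

  density <- withr::with_seed(seed, {
    base <- rlnorm(n, meanlog = log(120), sdlog = 0.9)
    for (ctr in urban_centers) {
      d2 <- (cx / cell_km - ctr$x)^2 + (cy / cell_km - ctr$y)^2
      base <- base + ctr$intensity * exp(-d2 / (2 * ctr$radius^2))
    }
    base
  })

  geometry <- lapply(seq_len(n), function(k) {
    x0 <- (col[k] - 1) * cell_km
    y0 <- (row[k] - 1) * cell_km
    x1 <- col[k] * cell_km
    y1 <- row[k] * cell_km
    cbind(
      x = c(x0, x1, x1, x0, x0),
      y = c(y0, y0, y1, y1, y0)
    )
  })

  out <- tibble(
    id = ids, row = row, col = col, x = cx, y = cy,
    area_km2 = cell_km^2,
    population = as.integer(round(density * cell_km^2)),
    geometry = geometry
  )
  class(out) <- c("area_set", class(out))
  out
}

default_urban_centers <- function(nx, ny) {
  list(list(
    x = nx / 2, y = ny / 2,
    radius = max(2, min(nx, ny) / 6),
    intensity = 3000
  ))
}

#' Write an area set as a GeoJSON FeatureCollection
#'
#' Planar coordinates; feature properties are `id`, `area_km2` and
#' `population`.
#'
#' @param areas An `area_set` tibble (see [make_lattice()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_areas <- function(areas, path) {
  check_area_set(areas)
  features <- lapply(seq_len(nrow(areas)), function(k) {
    ring <- areas$geometry[[k]]
    list(
      type = "Feature",
      properties = list(
        id = areas$id[k],
        area_km2 = areas$area_km2[k],
        population = areas$population[k]
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
          c(ring[i, 1], ring[i, 2])
        }))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# --- Gaussian random field machinery -----------------------------------

# Cholesky factor of an exponential covariance on a set of planar points.
# `range` is the e-folding correlation length in the same units as the
# coordinates. A small diagonal jitter keeps the factorization stable.
exp_cov_chol <- function(x, y, range) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  sigma <- exp(-d / range)
  diag(sigma) <- diag(sigma) + 1e-10
  chol(sigma)
}

# One draw of a zero-mean unit-variance field given the Cholesky factor.
grf_draw <- function(chol_upper) {
  as.numeric(crossprod(chol_upper, rnorm(nrow(chol_upper))))
}

# Stationary AR(1) series: marginal sd equals `sd` for any 0 <= rho < 1.
ar1_series <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  innov <- rnorm(n, sd = sd * sqrt(1 - rho^2))
  if (n == 1) return(innov / sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd)
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t]
  x
}
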