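#' Contiguity-based spatial weights
#'
#' Builds queen or rook contiguity from polygon geometry: two areas are
#' queen neighbors if their rings share at least one (snapped) vertex
#' and rook neighbors if they share at least two, i.e. a common edge.
#' This vertex-sharing rule is exact for lattice cells and for polygon
#' layers with conforming boundaries. Weights are binary or
#' row-standardized; areas without neighbors are reported as islands.
#'
#' @param areas An `area_set` tibble with a `geometry` list-column.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @param standardize Row-standardize the weights so each non-island
#'   row sums to one (default `TRUE`).
#' @param snap Coordinate snapping tolerance for vertex matching.
#' @return An object of class `spatial_weights`: list with `ids`,
#'   `neighbors` (list of integer indices), `weights` (list of numeric
#'   weights), `standardized`, `scheme` and `islands` (character ids).
#' @examples
#' w <- build_weights(make_lattice(3, 3, seed = 1), scheme = "queen")
#' lengths(w$neighbors)  # corners 3, edges 5, center 8
#' @export
build_weights <- function(areas, scheme = c("queen", "rook"),
                          standardize = TRUE, snap = 1e-8) {
  check_area_set(areas)
  scheme <- match.arg(scheme)
  n <- nrow(areas)
  if (n == 0) stop_frame("empty area set.")

  # vertex key -> area indices sharing that vertex
  vert <- lapply(seq_len(n), function(i) {
    ring <- areas$geometry[[i]]
    ring <- ring[-nrow(ring), , drop = FALSE]
    unique(paste(round(ring[, 1] / snap), round(ring[, 2] / snap)))
  })
  vmap <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    for (key in vert[[i]]) {
      vmap[[key]] <- c(vmap[[key]], i)
    }
  }
  shared <- matrix(0L, n, n)
  for (key in ls(vmap)) {
    members <- vmap[[key]]
    if (length(members) > 1) {
      for (a in members) shared[a, members] <- shared[a, members] + 1L
    }
  }
  diag(shared) <- 0L
  min_shared <- if (scheme == "queen") 1L else 2L
  adj <- shared >= min_shared

  neighbors <- apply(adj, 1, which, simplify = FALSE)
  weights <- lapply(neighbors, function(nb) {
    k <- length(nb)
    if (k == 0) numeric(0)
    else if (standardize) rep(1 / k, k)
    else rep(1, k)
  })
  islands <- areas$id[lengths(neighbors) == 0]
  structure(
    list(ids = areas$id, neighbors = neighbors, weights = weights,
         standardized = standardize, scheme = scheme, islands = islands),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf(
    "<spatial_weights> %d areas, %s contiguity, %s weights, %d island(s)\n",
    length(x$ids), x$scheme,
    if (x$standardized) "row-standardized" else "binary",
    length(x$islands)
  ))
  invisible(x)
}

#' Dense matrix form of spatial weights
#'
#' @param W A `spatial_weights` object.
#' @return An n x n numeric matrix with `w[i, j]` the weight of
#'   neighbor `j` for area `i` (zero elsewhere).
#' @export
weights_matrix <- function(W) {
  n <- length(W$ids)
  m <- matrix(0, n, n, dimnames = list(W$ids, W$ids))
  for (i in seq_len(n)) {
    m[i, W$neighbors[[i]]] <- W$weights[[i]]
  }
  m
}

#' Per-area temporal mean of a variable
#'
#' Reduces the panel to one value per area: the mean of the daily
#' values of `variable` over a date window (default: the full period).
#' This is the per-area input to the hot-spot analysis.
#'
#' @param panel A stressor panel tibble.
#' @param variable Variable to reduce.
#' @param window Optional length-2 date vector `c(start, end)`.
#' @return A tibble (`area_id`, `value`). Areas with no data in the
#'   window are excluded with a warning.
#' @export
period_mean_by_area <- function(panel, variable, window = NULL) {
  check_panel(panel)
  if (!variable %in% panel$variable) {
    stop_key(sprintf("variable `%s` is not present in the panel.", variable))
  }
  sub <- panel[panel$variable == variable, ]
  all_ids <- unique(sub$area_id)
  if (!is.null(window)) {
    window <- as.Date(window)
    sub <- sub[sub$date >= window[1] & sub$date <= window[2], ]
  }
  out <- sub |>
    dplyr::group_by(area_id = .data$area_id) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  missing_ids <- setdiff(all_ids, out$area_id)
  if (length(missing_ids)) {
    warn(sprintf("areas with no data in the window were excluded: %s",
                 paste(missing_ids, collapse = ", ")))
  }
  out
}
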