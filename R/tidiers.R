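#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation matrix
#'
#' @param x A `stressor_cormat`.
#' @param ... Unused.
#' @return A tibble with one row per unordered variable pair:
#'   `stratum`, `var_a`, `var_b`, `r`, `n`, `strength`.
#' @method tidy stressor_cormat
#' @export
tidy.stressor_cormat <- function(x, ...) {
  pairs <- utils::combn(x$variables, 2)
  idx <- t(pairs)
  tibble(
    stratum = x$stratum,
    var_a = pairs[1, ], var_b = pairs[2, ],
    r = x$r[idx],
    n = as.integer(x$n[idx]),
    strength = classify_strength(x$r[idx])
  )
}

#' @rdname tidy.stressor_cormat
#' @method glance stressor_cormat
#' @export
glance.stressor_cormat <- function(x, ...) {
  td <- tidy(x)
  tibble(
    stratum = x$stratum,
    n_variables = length(x$variables),
    n_pairs = nrow(td),
    n_defined = sum(!is.na(td$r)),
    max_abs_r = max(abs(td$r), na.rm = TRUE)
  )
}

#' Tidy a cross-correlation result
#'
#' @param x A `stressor_ccf`.
#' @param ... Unused.
#' @return The lag table with the pair labels as columns.
#' @method tidy stressor_ccf
#' @export
tidy.stressor_ccf <- function(x, ...) {
  tibble(
    x_name = attr(x, "x_name"), y_name = attr(x, "y_name"),
    lag_unit = attr(x, "lag_unit"),
    lag = x$lag, ccf = x$ccf, n_overlap = x$n_overlap
  )
}

#' @rdname tidy.stressor_ccf
#' @method glance stressor_ccf
#' @export
glance.stressor_ccf <- function(x, ...) {
  peak <- which.max(abs(x$ccf))
  tibble(
    x_name = attr(x, "x_name"), y_name = attr(x, "y_name"),
    lag_unit = attr(x, "lag_unit"),
    r_lag0 = x$ccf[x$lag == 0],
    peak_lag = x$lag[peak],
    peak_ccf = x$ccf[peak]
  )
}

#' Tidy / summarize a LISA result
#'
#' @param x A `lisa_result`.
#' @param ... Unused.
#' @return `tidy()` returns the per-area table as a plain tibble;
#'   `glance()` one row of cluster counts.
#' @method tidy lisa_result
#' @export
tidy.lisa_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.lisa_result
#' @method glance lisa_result
#' @export
glance.lisa_result <- function(x, ...) {
  tibble(
    variable = attr(x, "variable") %||% NA_character_,
    alpha = attr(x, "alpha"),
    n_areas = nrow(x),
    n_islands = sum(x$island),
    n_hot = sum(x$label == "HH", na.rm = TRUE),
    n_cold = sum(x$label == "LL", na.rm = TRUE),
    n_outlier = sum(x$label %in% c("HL", "LH"), na.rm = TRUE),
    n_ns = sum(x$label == "ns", na.rm = TRUE)
  )
}

#' Adjacency-list form of spatial weights
#'
#' @param x A `spatial_weights` object.
#' @param ... Unused.
#' @return A tibble `id`, `neighbor`, `weight` (one row per directed
#'   link).
#' @method tidy spatial_weights
#' @export
tidy.spatial_weights <- function(x, ...) {
  rows <- purrr::imap(x$neighbors, function(nb, i) {
    if (!length(nb)) return(NULL)
    tibble(id = x$ids[[i]], neighbor = x$ids[nb], weight = x$weights[[i]])
  })
  dplyr::bind_rows(rows)
}
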