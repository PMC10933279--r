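#' Region-mean daily series
#'
#' Collapses the panel over areas: for every variable and day, the
#' unweighted mean across all areas reporting that day. This is the
#' temporal-analysis framing in which the spatial separation into areas
#' is neglected.
#'
#' @param panel A stressor panel tibble.
#' @return A wide tibble with a `date` column and one column per
#'   variable, sorted by date. Missing days stay missing.
#' @export
bw_mean_series <- function(panel) {
  check_panel(panel)
  panel |>
    dplyr::group_by(.data$date, .data$variable) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    dplyr::arrange(.data$date)
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson coefficients over the rows of `records`.
#' Rows are the observation units: days (region-mean mode) or area-days
#' (pooled mode). Entries where a variable is constant over the
#' overlap, or where fewer than two complete pairs exist, are undefined
#' and returned as `NA` (flagged, not zero).
#'
#' @param records A tibble whose columns include `variables`.
#' @param variables Variables to correlate; defaults to all numeric
#'   columns except identifiers.
#' @param stratum Label carried with the matrix (e.g. `"all"`,
#'   `"month=01"`, `"density=4"`).
#' @return An object of class `stressor_cormat`: a list with elements
#'   `variables`, `r` (symmetric matrix), `n` (pairwise complete
#'   counts) and `stratum`. Use [tidy()] for a long tibble.
#' @examples
#' m <- correlation_matrix(tibble::tibble(a = 1:4, b = c(2, 1, 4, 3)))
#' m$r["a", "b"]  # 0.6
#' @export
correlation_matrix <- function(records, variables = NULL, stratum = "all") {
  if (is.null(variables)) {
    variables <- setdiff(
      names(records)[vapply(records, is.numeric, logical(1))],
      c("area_id", "date")
    )
  }
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars)) {
    stop_frame(sprintf("variables not in `records`: %s",
                       paste(missing_vars, collapse = ", ")))
  }
  m <- as.matrix(records[, variables, drop = FALSE])
  n_pair <- crossprod(!is.na(m))
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  r[n_pair < 2] <- NA_real_
  # unit diagonal only where the variable actually varies
  v <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    length(col) >= 2 && sd(col) > 0
  })
  diag(r) <- ifelse(v, 1, NA_real_)
  structure(
    list(variables = variables, r = r, n = n_pair, stratum = stratum),
    class = "stressor_cormat"
  )
}

#' @export
print.stressor_cormat <- function(x, digits = 2, ...) {
  cat(sprintf("<stressor_cormat> stratum = %s, %d variables\n",
              x$stratum, length(x$variables)))
  print(round(x$r, digits))
  invisible(x)
}

#' Correlation-strength taxonomy
#'
#' Classifies the magnitude of a Pearson coefficient:
#' `|r| > 0.9` almost perfect, `(0.7, 0.9]` very large, `(0.5, 0.7]`
#' large, `(0.3, 0.5]` moderate, `(0.1, 0.3]` small, `<= 0.1` trivial.
#' The exact point 0.1 is assigned to "trivial" so the scheme is total
#' on `[-1, 1]`.
#'
#' @param r Pearson coefficient(s) in `[-1, 1]`; `NA` passes through.
#' @return An ordered factor with levels from `trivial` to
#'   `almost perfect`.
#' @examples
#' classify_strength(c(0.94, -0.68, 0.1))
#' @export
classify_strength <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop_domain("`r` must lie in [-1, 1].")
  }
  lv <- c("trivial", "small", "moderate", "large", "very large",
          "almost perfect")
  a <- abs(r)
  idx <- 1L + (a > 0.1) + (a > 0.3) + (a > 0.5) + (a > 0.7) + (a > 0.9)
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Calendar-month correlation matrices
#'
#' One Pearson matrix per calendar month (pooled across years). In
#' `"bwmean"` mode (default) the units are region-mean days from
#' [bw_mean_series()]; in `"pooled"` mode they are area-days.
#'
#' @param panel A stressor panel tibble.
#' @param mode `"bwmean"` or `"pooled"`.
#' @param variables Variables to include (default: the eight stressors
#'   present in the panel).
#' @return A named list of 12 `stressor_cormat`s, names `"01"`-`"12"`.
#'   Months with fewer than two units give all-`NA` matrices.
#' @export
monthly_matrices <- function(panel, mode = c("bwmean", "pooled"),
                             variables = NULL) {
  check_panel(panel)
  mode <- match.arg(mode)
  variables <- variables %||%
    intersect(stressor_variables, unique(panel$variable))
  records <- if (mode == "bwmean") {
    bw_mean_series(panel)
  } else {
    tidyr::pivot_wider(panel, names_from = "variable",
                       values_from = "value")
  }
  months <- sprintf("%02d", 1:12)
  out <- lapply(months, function(mm) {
    sub <- records[format(records$date, "%m") == mm, , drop = FALSE]
    correlation_matrix(sub, variables, stratum = paste0("month=", mm))
  })
  names(out) <- months
  out
}

#' Count sign changes between two correlation matrices
#'
#' Number of unordered off-diagonal variable pairs whose coefficients
#' have strictly opposite signs in `m1` and `m2`. A zero coefficient
#' never participates in a change; pairs undefined in either matrix are
#' skipped.
#'
#' @param m1,m2 `stressor_cormat`s over the same ordered variables.
#' @return A list of class `sign_change`: `count`, `pairs` (tibble of
#'   flipped pairs with both coefficients), `total_pairs`
#'   (`choose(V, 2)`) and `compared` (pairs defined in both).
#' @export
sign_change_count <- function(m1, m2) {
  if (!identical(m1$variables, m2$variables)) {
    stop_frame("matrices have different variable orderings.")
  }
  v <- m1$variables
  pairs <- utils::combn(v, 2)
  r1 <- m1$r[t(pairs)]
  r2 <- m2$r[t(pairs)]
  defined <- !is.na(r1) & !is.na(r2)
  flip <- defined & (sign(r1) * sign(r2) < 0)
  structure(
    list(
      count = sum(flip),
      pairs = tibble(
        var_a = pairs[1, flip], var_b = pairs[2, flip],
        r_a = r1[flip], r_b = r2[flip]
      ),
      total_pairs = ncol(pairs),
      compared = sum(defined),
      strata = c(m1$stratum, m2$stratum)
    ),
    class = "sign_change"
  )
}

#' @export
print.sign_change <- function(x, ...) {
  cat(sprintf("%d of %d pairs changed sign (%s vs %s)\n",
              x$count, x$total_pairs, x$strata[1], x$strata[2]))
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}

#' Lagged cross-correlation of two aligned series
#'
#' For each lag `k` in `-max_lag..max_lag`, the Pearson correlation of
#' the pairs `(x(t), y(t + k))` over the overlap window where both are
#' observed, using that window's own means and sums of squares in both
#' numerator and denominator (which keeps every coefficient in
#' `[-1, 1]`). Positive lags pull future values of `y` back against
#' `x`, so a peak at `k > 0` means `x` leads `y` by `k` steps.
#'
#' @param x,y Numeric vectors of equal length (`NA`s allowed).
#' @param max_lag Maximum |lag|; the series must have length at least
#'   `max_lag + 2`.
#' @param lag_unit `"day"` or `"month"`, recorded in the result.
#' @param x_name,y_name Labels for the two series.
#' @return A tibble of class `stressor_ccf` with columns `lag`, `ccf`,
#'   `n_overlap`; attributes record the pair, the lag unit and the sign
#'   convention. Lags whose overlap has fewer than two complete pairs
#'   or zero variance are `NA`.
#' @examples
#' x <- sin(2 * pi * (1:730) / 365)
#' cc <- cross_correlation(x, x, max_lag = 10)
#' cc$ccf[cc$lag == 0]  # 1
#' @export
cross_correlation <- function(x, y, max_lag, lag_unit = c("day", "month"),
                              x_name = "x", y_name = "y") {
  lag_unit <- match.arg(lag_unit)
  if (length(x) != length(y)) {
    stop_frame("`x` and `y` must be aligned series of equal length.")
  }
  n <- length(x)
  if (n < max_lag + 2) {
    stop_domain("series too short for the requested `max_lag`.")
  }
  lags <- seq.int(-max_lag, max_lag)
  res <- lapply(lags, function(k) {
    t <- seq.int(max(1L, 1L - k), min(n, n - k))
    xs <- x[t]
    ys <- y[t + k]
    ok <- !is.na(xs) & !is.na(ys)
    xs <- xs[ok]; ys <- ys[ok]
    if (length(xs) < 2 || sd(xs) == 0 || sd(ys) == 0) {
      c(NA_real_, length(xs))
    } else {
      c(cor(xs, ys), length(xs))
    }
  })
  out <- tibble(
    lag = lags,
    ccf = vapply(res, `[`, numeric(1), 1),
    n_overlap = as.integer(vapply(res, `[`, numeric(1), 2))
  )
  attr(out, "x_name") <- x_name
  attr(out, "y_name") <- y_name
  attr(out, "lag_unit") <- lag_unit
  attr(out, "convention") <-
    sprintf("positive lag: %s leads %s", x_name, y_name)
  class(out) <- c("stressor_ccf", class(out))
  out
}

#' Autocorrelation function of a series
#'
#' [cross_correlation()] of a series with itself; the lag-0 coefficient
#' is 1 whenever the series varies.
#'
#' @inheritParams cross_correlation
#' @return A `stressor_ccf` tibble.
#' @export
autocorrelation <- function(x, max_lag, lag_unit = "day", x_name = "x") {
  cross_correlation(x, x, max_lag, lag_unit = lag_unit,
                    x_name = x_name, y_name = x_name)
}

#' Cross-correlation at monthly resolution
#'
#' Aggregates the region-mean daily series of two variables to calendar
#' month means, then computes the lagged cross-correlation with
#' `lag_unit = "month"`.
#'
#' @param panel A stressor panel tibble.
#' @param x_name,y_name Variable names present in the panel.
#' @param max_lag_months Maximum |lag| in months.
#' @return A `stressor_ccf` tibble.
#' @export
monthly_ccf <- function(panel, x_name, y_name, max_lag_months) {
  check_panel(panel)
  for (v in c(x_name, y_name)) {
    if (!v %in% panel$variable) {
      stop_key(sprintf("variable `%s` is not present in the panel.", v))
    }
  }
  series <- bw_mean_series(panel)
  monthly <- series |>
    dplyr::mutate(month = format(.data$date, "%Y-%m")) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c(x_name, y_name)),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::arrange(.data$month)
  if (nrow(monthly) < max_lag_months + 2) {
    stop_domain("panel spans too few months for the requested lag.")
  }
  cross_correlation(monthly[[x_name]], monthly[[y_name]], max_lag_months,
                    lag_unit = "month", x_name = x_name, y_name = y_name)
}
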