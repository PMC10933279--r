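#' Local Moran's I
#'
#' The per-area local Moran statistic
#' \deqn{I_i = \frac{x_i - \bar X}{S_i^2} \sum_{j \ne i} w_{ij} (x_j - \bar X)}
#' where \eqn{\bar X} is the global mean over the included areas and
#' the normalizer is, by default, the leave-one-out second moment
#' \eqn{S_i^2 = \sum_{j \ne i} (x_j - \bar X)^2 / (n - 1)}
#' (`variance = "leave_one_out"`). The alternative
#' `variance = "global"` uses the global second moment
#' \eqn{m_2 = \sum_j (x_j - \bar X)^2 / n}, under which the mean of the
#' \eqn{I_i} over areas equals the global Moran's I exactly for
#' row-standardized weights. Islands carry no statistic and are
#' excluded from the mean and the moments. Conditional-permutation
#' p-values are identical under the two variants because the
#' normalizer is fixed per area under permutation of the remaining
#' values.
#'
#' @param values A tibble (`area_id`, `value`) as from
#'   [period_mean_by_area()], or a numeric vector named by area id.
#' @param W A [build_weights()] object.
#' @param variance `"leave_one_out"` (default) or `"global"`.
#' @return A tibble of class `local_moran`: `area_id`, `value`,
#'   `deviation` (`x_i - mean`), `lag` (weighted neighbor deviation
#'   sum), `I`, `island`.
#' @export
local_moran <- function(values, W, variance = c("leave_one_out", "global")) {
  variance <- match.arg(variance)
  x <- align_values(values, W)
  inc <- !is.na(x) & !(W$ids %in% W$islands)
  if (sum(inc) < 3) {
    stop_domain("need at least 3 non-island areas with data.")
  }
  xbar <- mean(x[inc])
  z <- x - xbar
  q <- sum(z[inc]^2)
  if (q == 0) {
    abort("values are constant; local Moran's I is undefined.",
          class = "stressorscape_degenerate_error")
  }
  n_inc <- sum(inc)
  lag <- vapply(seq_along(x), function(i) {
    if (!inc[i]) return(NA_real_)
    nb <- W$neighbors[[i]]
    w <- W$weights[[i]]
    keep <- inc[nb]
    sum(w[keep] * z[nb[keep]])
  }, numeric(1))
  s2 <- switch(variance,
    leave_one_out = (q - ifelse(inc, z^2, NA_real_)) / (n_inc - 1),
    global = rep(q / n_inc, length(x))
  )
  I <- ifelse(inc, z / s2 * lag, NA_real_)
  out <- tibble(
    area_id = W$ids, value = x, deviation = ifelse(inc, z, NA_real_),
    lag = lag, I = I, island = W$ids %in% W$islands
  )
  attr(out, "mean") <- xbar
  attr(out, "variance") <- variance
  class(out) <- c("local_moran", class(out))
  out
}

align_values <- function(values, W) {
  if (is.data.frame(values)) {
    if (!all(c("area_id", "value") %in% names(values))) {
      stop_schema("`values` must have columns `area_id` and `value`.")
    }
    x <- values$value[match(W$ids, values$area_id)]
  } else if (!is.null(names(values))) {
    x <- unname(values[W$ids])
  } else {
    if (length(values) != length(W$ids)) {
      stop_frame("unnamed `values` must match the weights' area order.")
    }
    x <- as.numeric(values)
  }
  x
}

#' Conditional-permutation pseudo p-values for local Moran's I
#'
#' For each area the observed value is held fixed while the remaining
#' n-1 values are randomly reassigned to its neighbor positions
#' (`n_perm` draws, one shared set of random index rows reused across
#' areas), and the local Moran statistic is recomputed. The directional
#' tail count R is the number of permuted statistics at least as
#' extreme as the observed one on the observed sign's side, giving the
#' one-sided pseudo p-value `(R + 1) / (n_perm + 1)`. The default
#' `alternative = "two.sided"` doubles that tail (capped at 1), which
#' keeps the test calibrated: under a spatially random field the
#' fraction of areas with p below alpha is about alpha. The GeoDa-style
#' folded one-sided value is available as `"directional"` (its null
#' rejection rate is about twice nominal).
#'
#' @inheritParams local_moran
#' @param n_perm Number of permutations (at least 99). With `n_perm`
#'   permutations the smallest attainable directional p is
#'   `1 / (n_perm + 1)`.
#' @param seed Optional integer seed (recommended for reproducibility).
#' @param alternative `"two.sided"` (default), `"directional"`,
#'   `"greater"` or `"less"`.
#' @return A tibble (`area_id`, `I`, `p`, `island`); p is `NA` for
#'   islands. Attributes record `n_perm`, `alternative` and `seed`.
#' @export
permutation_pvalues <- function(values, W, n_perm = 999, seed = NULL,
                                alternative = c("two.sided", "directional",
                                                "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) {
    stop_config("`n_perm` must be at least 99 for stable significance bins.")
  }
  lm <- local_moran(values, W, variance = "leave_one_out")
  x <- lm$value
  inc <- !is.na(lm$I)
  xbar <- attr(lm, "mean")
  z <- x - xbar
  q <- sum(z[inc]^2)
  n_inc <- sum(inc)
  idx_inc <- which(inc)
  pos_of <- match(seq_along(x), idx_inc)  # position among included

  max_k <- max(1L, max(lengths(W$neighbors)[inc]))
  draw <- function() {
    rids <- t(vapply(seq_len(n_perm),
                     function(r) sample.int(n_inc - 1L, max_k),
                     integer(max_k)))
    p <- rep(NA_real_, length(x))
    z_inc <- z[idx_inc]
    for (i in idx_inc) {
      nb <- W$neighbors[[i]]
      keep <- inc[nb]
      w <- W$weights[[i]][keep]
      k <- length(w)
      if (k == 0) next
      others <- z_inc[-pos_of[i]]
      sel <- rids[, seq_len(k), drop = FALSE]
      lag_perm <- matrix(others[sel], nrow = n_perm) %*% w
      s2 <- (q - z[i]^2) / (n_inc - 1)
      I_perm <- z[i] / s2 * lag_perm
      I_obs <- lm$I[i]
      r_up <- sum(I_perm >= I_obs)
      r_dn <- sum(I_perm <= I_obs)
      p[i] <- switch(alternative,
        greater = (r_up + 1) / (n_perm + 1),
        less = (r_dn + 1) / (n_perm + 1),
        directional = (if (I_obs >= 0) r_up + 1 else r_dn + 1) / (n_perm + 1),
        two.sided = min(
          1, 2 * (if (I_obs >= 0) r_up + 1 else r_dn + 1) / (n_perm + 1)
        )
      )
    }
    p
  }
  p <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- tibble(area_id = lm$area_id, I = lm$I, p = p, island = lm$island)
  attr(out, "n_perm") <- n_perm
  attr(out, "alternative") <- alternative
  attr(out, "seed") <- seed
  out
}

#' Hot/cold-spot quadrant classification
#'
#' Classifies every non-island area into a Moran-scatterplot quadrant:
#' `HH` (hot spot: value and spatial lag both above the mean), `LL`
#' (cold spot), `HL`/`LH` (spatial outliers). Areas with `p > alpha`
#' are labeled `ns`; quadrants are reported for all areas regardless of
#' significance in the `quadrant` column, while `label` carries the
#' thresholded classification.
#'
#' @inheritParams local_moran
#' @param p A tibble from [permutation_pvalues()] (or a numeric vector
#'   aligned with `W$ids`).
#' @param alpha Significance level for the `label` column.
#' @return A tibble of class `lisa_result`: `area_id`, `value`,
#'   `deviation`, `lag`, `I`, `p`, `quadrant`, `label`, `sig_bin`,
#'   `island`.
#' @export
classify_quadrants <- function(values, W, p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_domain("`alpha` must be in (0, 1).")
  lm <- local_moran(values, W)
  pv <- if (is.data.frame(p)) {
    if (!identical(p$area_id, lm$area_id)) {
      stop_frame("`p` is not aligned with the weights' areas.")
    }
    p$p
  } else {
    if (length(p) != nrow(lm)) stop_frame("`p` has the wrong length.")
    as.numeric(p)
  }
  quadrant <- dplyr::case_when(
    is.na(lm$I) ~ NA_character_,
    lm$deviation > 0 & lm$lag > 0 ~ "HH",
    lm$deviation <= 0 & lm$lag <= 0 ~ "LL",
    lm$deviation > 0 & lm$lag <= 0 ~ "HL",
    TRUE ~ "LH"
  )
  label <- dplyr::if_else(
    !is.na(pv) & pv <= alpha & !is.na(quadrant), quadrant, "ns"
  )
  out <- tibble(
    area_id = lm$area_id, value = lm$value, deviation = lm$deviation,
    lag = lm$lag, I = lm$I, p = pv,
    quadrant = quadrant, label = label,
    sig_bin = significance_bins_na(pv),
    island = lm$island
  )
  attr(out, "alpha") <- alpha
  class(out) <- c("lisa_result", class(out))
  out
}

#' Significance bins for pseudo p-values
#'
#' Maps p-values to the display bins `0.001` (p < 0.001), `0.01`
#' (p < 0.01), `0.05` (p < 0.05) and `ns` otherwise.
#'
#' @param p p-values in `(0, 1]`.
#' @return A factor with levels `ns`, `0.05`, `0.01`, `0.001`.
#' @export
significance_bins <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop_domain("`p` must lie in (0, 1].")
  }
  significance_bins_na(p)
}

significance_bins_na <- function(p) {
  lv <- c("ns", "0.05", "0.01", "0.001")
  idx <- ifelse(is.na(p), NA_integer_,
                1L + (p < 0.05) + (p < 0.01) + (p < 0.001))
  factor(lv[idx], levels = lv)
}

#' One-call LISA hot-spot analysis of a panel variable
#'
#' Convenience wrapper: reduces the panel to per-area period means,
#' builds contiguity weights, runs the conditional permutation test and
#' classifies quadrants.
#'
#' @param panel A stressor panel tibble.
#' @param areas The matching `area_set`.
#' @param variable Variable to analyze.
#' @param window Optional date window passed to
#'   [period_mean_by_area()].
#' @param scheme Contiguity scheme for [build_weights()].
#' @param n_perm,seed,alternative Passed to [permutation_pvalues()].
#' @param alpha Significance level for [classify_quadrants()].
#' @return A `lisa_result` tibble.
#' @export
lisa_hotspots <- function(panel, areas, variable, window = NULL,
                          scheme = "queen", n_perm = 999, seed = NULL,
                          alternative = "two.sided", alpha = 0.05) {
  W <- build_weights(areas, scheme = scheme, standardize = TRUE)
  vals <- period_mean_by_area(panel, variable, window)
  p <- permutation_pvalues(vals, W, n_perm = n_perm, seed = seed,
                           alternative = alternative)
  out <- classify_quadrants(vals, W, p, alpha = alpha)
  attr(out, "variable") <- variable
  out
}

#' Write a LISA result as GeoJSON
#'
#' @param lisa A `lisa_result` tibble.
#' @param areas The `area_set` providing the polygons.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lisa_geojson <- function(lisa, areas, path) {
  check_area_set(areas)
  m <- match(areas$id, lisa$area_id)
  features <- lapply(seq_len(nrow(areas)), function(k) {
    ring <- areas$geometry[[k]]
    row <- lisa[m[k], ]
    list(
      type = "Feature",
      properties = list(
        id = areas$id[k],
        I = row$I, p = row$p,
        quadrant = row$quadrant, label = row$label,
        sig_bin = as.character(row$sig_bin), island = row$island
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
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
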