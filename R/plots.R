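#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a correlation matrix
#'
#' @param object A `stressor_cormat`.
#' @param digits Digits printed in the tiles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stressor_cormat <- function(object, digits = 2, ...) {
  td <- tidy(object)
  both <- dplyr::bind_rows(
    td,
    dplyr::rename(td, var_a = "var_b", var_b = "var_a")
  )
  both$var_a <- factor(both$var_a, levels = object$variables)
  both$var_b <- factor(both$var_b, levels = rev(object$variables))
  ggplot2::ggplot(both, ggplot2::aes(.data$var_a, .data$var_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$r, digits)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = sprintf("Pearson correlations (%s)",
                                  object$stratum)) +
    ggplot2::theme_minimal()
}

#' Lollipop plot of a cross-correlation function
#'
#' @param object A `stressor_ccf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stressor_ccf <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$ccf)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::labs(
      x = sprintf("lag (%ss)", attr(object, "lag_unit")),
      y = "ccf",
      title = sprintf("%s vs %s", attr(object, "x_name"),
                      attr(object, "y_name")),
      subtitle = attr(object, "convention")
    ) +
    ggplot2::theme_minimal()
}

#' Map of LISA hot and cold spots
#'
#' Draws the area polygons filled by cluster label (hot spots red, cold
#' spots blue, spatial outliers muted, non-significant grey).
#'
#' @param object A `lisa_result`.
#' @param areas The `area_set` providing polygons.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lisa_result <- function(object, areas, ...) {
  check_area_set(areas)
  polys <- purrr::map2_dfr(areas$id, areas$geometry, function(id, ring) {
    tibble(area_id = id, px = ring[, 1], py = ring[, 2])
  })
  polys <- dplyr::left_join(
    polys, tidy(object)[, c("area_id", "label", "island")],
    by = "area_id"
  )
  polys$label[polys$island] <- "isolated"
  cols <- c(HH = "firebrick", LL = "steelblue", HL = "rosybrown2",
            LH = "lightsteelblue", ns = "grey90", isolated = "grey40")
  ggplot2::ggplot(polys, ggplot2::aes(.data$px, .data$py,
                                      group = .data$area_id,
                                      fill = .data$label)) +
    ggplot2::geom_polygon(color = "white", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = cols, name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("LISA clusters: %s",
                                  attr(object, "variable") %||% "")) +
    ggplot2::theme_void()
}
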