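#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: predictor stacks as faceted tile maps, richness surfaces as a
#' single tile map, fitted ESMs as a sub-model weight chart, and Lee's L
#' results as the significance-class map.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @method autoplot predictor_stack
#' @export
autoplot.predictor_stack <- function(object, ...) {
  df <- as_tibble.predictor_stack(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~predictor) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "z")
}

#' @rdname autoplot-methods
#' @method autoplot richness_map
#' @export
autoplot.richness_map <- function(object, ...) {
  df <- layer_coords(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80", option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "richness",
                  title = paste("Richness:", attr(object, "guild") %||% "all"))
}

#' @rdname autoplot-methods
#' @method autoplot esm_model
#' @export
autoplot.esm_model <- function(object, ...) {
  df <- tidy.esm_model(object)
  df$pair <- paste(df$var1, df$var2, sep = ":")
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$somers_d,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~technique) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "bivariate model", y = "Somers' D",
                  fill = "retained")
}

#' @rdname autoplot-methods
#' @method autoplot lee_result
#' @export
autoplot.lee_result <- function(object, ...) {
  df <- tidy.lee_result(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(negative = "#b2182b", not_significant = "grey85",
                 positive = "#2166ac"), na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Lee's L class")
}
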