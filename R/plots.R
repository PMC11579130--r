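# ggplot2 visualisation helpers.

#' @importFrom rlang .data
NULL

mask_to_df <- function(labels) {
  tibble::tibble(row = as.vector(row(labels)),
                 col = as.vector(col(labels)),
                 label = factor(as.vector(labels), levels = 0:6,
                                labels = c("background", "I", "II", "III",
                                           "IV", "V", "VI")))
}

# The layer colour code used throughout: I red, II orange, III yellow,
# IV green, V blue, VI grey.
LAYER_COLOURS <- c(background = "white", I = "#d53e4f", II = "#fc8d59",
                   III = "#fee08b", IV = "#99d594", V = "#3288bd",
                   VI = "#999999")

#' Plot a layer mask
#'
#' @param mask A [layer_mask()].
#' @return A ggplot object.
#' @export
plot_layer_mask <- function(mask) {
  stopifnot(inherits(mask, "layer_mask"))
  df <- mask_to_df(mask$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = LAYER_COLOURS, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "layer") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cortex phantom (image and ground truth side by side)
#'
#' @param object A [generate_phantom()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phantom
#' @export
autoplot.phantom <- function(object, ...) {
  g <- to_gray(object$image$pixels)
  df <- tibble::tibble(row = as.vector(row(g)), col = as.vector(col(g)),
                       value = as.vector(g))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity",
                  title = sprintf("phantom (seed %d)",
                                  object$config$seed)) +
    ggplot2::theme_minimal()
}

#' Plot a metrics report (per-layer metric bars)
#'
#' @param object A [evaluate()] metrics report.
#' @param metrics Character vector of per-layer columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object,
                                    metrics = c("iou", "dsc", "recall",
                                                "precision"), ...) {
  df <- object$per_layer
  long <- dplyr::bind_rows(lapply(metrics, function(m)
    tibble::tibble(class = df$class, metric = m, value = df[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$class),
                                     y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cortical layer", y = "score", fill = NULL) +
    ggplot2::theme_minimal()
}
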