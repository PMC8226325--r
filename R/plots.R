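#' Plot package objects with ggplot2
#'
#' `autoplot()` methods for the package's result types: an
#' [annotated_image()] draws the pixel raster with its ground-truth boxes
#' overlaid; a `prob_map` draws the per-pixel occlusion-placement weight as
#' a heat map (the warm/cold rendering of the map is visualisation only —
#' sampling uses the raw weights); a `cutout_result` shows the augmented
#' image with the erased rectangles outlined.
#'
#' @param object The object to plot.
#' @param boxes Overlay ground-truth boxes (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-earcount
NULL

raster_df <- function(pixels) {
  d <- dim(pixels)
  df <- tidyr::expand_grid(y = seq_len(d[1]) - 1L, x = seq_len(d[2]) - 1L)
  df$fill <- grDevices::rgb(as.vector(pixels[, , 1]) / 255,
                            as.vector(pixels[, , 2]) / 255,
                            as.vector(pixels[, , 3]) / 255)[
    (df$x) * d[1] + df$y + 1L]
  df
}

#' @rdname autoplot-earcount
#' @exportS3Method ggplot2::autoplot
autoplot.annotated_image <- function(object, boxes = TRUE, ...) {
  df <- raster_df(object$pixels)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_raster(ggplot2::aes(.data$x, .data$y), fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", title = object$image_id)
  if (boxes && nrow(object$boxes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$boxes,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmin + .data$width,
                   ymin = .data$ymin, ymax = .data$ymin + .data$height),
      colour = "yellow", fill = NA, linewidth = 0.3
    )
  }
  p
}

#' @rdname autoplot-earcount
#' @exportS3Method ggplot2::autoplot
autoplot.cutout_result <- function(object, boxes = TRUE, ...) {
  p <- autoplot.annotated_image(object$image, boxes = boxes)
  if (nrow(object$rectangles) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$rectangles,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1 + 1,
                   ymin = .data$y0, ymax = .data$y1 + 1),
      colour = "red", fill = NA, linetype = "dashed", linewidth = 0.4
    )
  }
  p
}

#' Plot per-stratum missed-detection rates
#'
#' @param rates The tibble returned by [stratified_missed_rate()].
#' @return A ggplot bar chart of missed-detection rate by stratum.
#' @export
plot_missed_rates <- function(rates) {
  ggplot2::ggplot(rates,
                  ggplot2::aes(.data$stratum, .data$missed_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "missed-detection rate",
                  title = "Missed detections by occlusion type")
}
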