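#' Build the occlusion-placement probability map
#'
#' The augmentation places simulated occlusions preferentially where ears
#' are dense. The per-pixel placement weight is
#'
#'   `I_i = 0.001 + 0.003 * n_i`
#'
#' where `n_i` is the number of ground-truth boxes whose half-open extent
#' contains pixel `i` (integer coordinates `x = col`, `y = row`, 0-based).
#' Every pixel keeps the background floor 0.001, so occlusions can also land
#' in sparse areas — as they do in the field, where leaves and stems occlude
#' isolated ears. The counts are accumulated as integers and the affine
#' formula applied once, so the result is bit-identical to evaluating the
#' formula pixel by pixel.
#'
#' @param image_size Integer `(rows, cols)`.
#' @param boxes A box table, already clipped to the grid (see
#'   [clip_boxes()]).
#' @return A `prob_map`: a `rows x cols` numeric matrix of weights with the
#'   box-count matrix attached as attribute `counts`.
#' @examples
#' m <- build_probability_map(c(10, 10), box_tbl(2, 2, 3, 3))
#' sum(m == 0.004) # 9 pixels covered by the box
#' @export
build_probability_map <- function(image_size, boxes) {
  stopifnot(length(image_size) == 2, all(image_size >= 1))
  rows <- as.integer(image_size[1])
  cols <- as.integer(image_size[2])
  counts <- matrix(0L, rows, cols)
  for (i in seq_len(nrow(boxes))) {
    # integer pixels x with xmin <= x < xmin + width
    c0 <- max(0L, as.integer(ceiling(boxes$xmin[i])))
    c1 <- min(cols - 1L, ceiling_half_open(boxes$xmin[i] + boxes$width[i]))
    r0 <- max(0L, as.integer(ceiling(boxes$ymin[i])))
    r1 <- min(rows - 1L, ceiling_half_open(boxes$ymin[i] + boxes$height[i]))
    if (c0 > c1 || r0 > r1) next
    counts[(r0:r1) + 1L, (c0:c1) + 1L] <-
      counts[(r0:r1) + 1L, (c0:c1) + 1L] + 1L
  }
  structure(0.001 + 0.003 * counts, counts = counts, class = "prob_map")
}

# largest integer strictly below x (upper end of the half-open interval)
ceiling_half_open <- function(x) {
  as.integer(ceiling(x)) - 1L
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map> %d x %d px, values in [%g, %g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Normalise a probability map to a sampling distribution
#'
#' Divides the map by its total mass so the result sums to 1; the ordering
#' of pixel masses is preserved, and the operation is idempotent. The
#' background floor of 0.001 guarantees positive total mass.
#'
#' @param map A `prob_map` (or any non-negative matrix with positive sum).
#' @return A numeric matrix of the same shape summing to 1.
#' @export
normalize_to_distribution <- function(map) {
  stopifnot(length(map) >= 1)
  total <- sum(map)
  if (total <= 0) abort("probability map has no mass")
  out <- unclass(map) / total
  attr(out, "counts") <- NULL
  out
}

#' @rdname autoplot-earcount
#' @exportS3Method ggplot2::autoplot
autoplot.prob_map <- function(object, ...) {
  df <- tidyr::expand_grid(
    y = seq_len(nrow(object)) - 1L,
    x = seq_len(ncol(object)) - 1L
  )
  df$value <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "I") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Occlusion-placement probability map")
}
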