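#' Configure the Random-Cutout augmentation
#'
#' Random-Cutout erases rectangles whose *positions* follow ear density (via
#' the probability map) and whose *sizes* scale with the ears present in the
#' image. With the default divisors, an image with `N_total` ears receives
#' `N = N_total / 4` rectangles (floored, minimum 1), each with height drawn
#' uniformly from `[H_min/4, H_max/4]` and width from `[W_min/4, W_max/4]`,
#' where the min/max are taken over the image's own box heights and widths.
#'
#' @param n_rect_divisor Divisor for the rectangle count (default 4).
#' @param size_divisor Divisor for the per-image size bounds (default 4).
#' @param fill Erase fill: `"white"` (channel max), `"random_noise"`, or
#'   `"mean"` (per-channel image mean).
#' @param seed Integer RNG seed.
#' @return A `cutout_config` list.
#' @export
cutout_config <- function(n_rect_divisor = 4, size_divisor = 4,
                          fill = c("white", "random_noise", "mean"),
                          seed = NULL) {
  fill <- match.arg(fill)
  stopifnot(n_rect_divisor >= 1, size_divisor >= 1)
  structure(list(n_rect_divisor = n_rect_divisor,
                 size_divisor = size_divisor, fill = fill, seed = seed),
            class = "cutout_config")
}

#' Sample occlusion centre points from a probability map
#'
#' Draws `n` distinct pixel coordinates without replacement, with
#' probability proportional to the (normalised) map. This collapses the
#' two-stage candidate-pool-then-subselect scheme into direct weighted
#' sampling, which draws centres from the same distribution.
#'
#' @param map A `prob_map` (or non-negative weight matrix).
#' @param n Number of centres (`0 <= n <=` number of pixels).
#' @param seed Integer RNG seed.
#' @return A tibble with 0-based pixel coordinates `x`, `y`, one row per
#'   centre, in draw order.
#' @export
propose_centers <- function(map, n, seed = NULL) {
  stopifnot(n >= 0)
  npix <- length(map)
  if (n > npix) abort("cannot sample more centres than there are pixels")
  local_seed(seed)
  if (n == 0) return(tibble::tibble(x = integer(), y = integer()))
  p <- normalize_to_distribution(map)
  idx <- sample.int(npix, n, replace = FALSE, prob = as.vector(p))
  rows <- nrow(map)
  tibble::tibble(x = (idx - 1L) %/% rows, y = (idx - 1L) %% rows)
}

#' Sample erase-rectangle sizes from the ears in an image
#'
#' Heights are uniform on `[H_min/d, H_max/d]` and widths on
#' `[W_min/d, W_max/d]`, where the bounds are the extreme box heights and
#' widths in the image and `d` is `size_divisor`. Realised pixel sizes are
#' rounded with a floor of 1 pixel. When `n > 1`, all heights are drawn
#' first, then all widths, in centre order.
#'
#' @param boxes A non-empty box table for the image.
#' @param size_divisor Divisor `d` (default 4).
#' @param n Number of sizes to draw.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `height_sampled`, `width_sampled`
#'   (continuous draws) and `height`, `width` (rounded, >= 1 px).
#' @export
sample_rectangle_size <- function(boxes, size_divisor = 4, n = 1,
                                  seed = NULL) {
  if (nrow(boxes) == 0) abort("no boxes: nothing to scale rectangle sizes to")
  local_seed(seed)
  h_rng <- range(boxes$height) / size_divisor
  w_rng <- range(boxes$width) / size_divisor
  hs <- runif(n, h_rng[1], h_rng[2])
  ws <- runif(n, w_rng[1], w_rng[2])
  tibble::tibble(
    height_sampled = hs, width_sampled = ws,
    height = pmax(1L, as.integer(round(hs))),
    width = pmax(1L, as.integer(round(ws)))
  )
}

# Clipped integer pixel extents of rectangles centred at (x, y).
rect_extents <- function(x, y, height, width, image_size) {
  rows <- image_size[1]; cols <- image_size[2]
  x0 <- x - (width - 1L) %/% 2L
  y0 <- y - (height - 1L) %/% 2L
  tibble::tibble(
    x0 = pmax(0L, x0), y0 = pmax(0L, y0),
    x1 = pmin(cols - 1L, x0 + width - 1L),
    y1 = pmin(rows - 1L, y0 + height - 1L)
  )
}

erase_rects <- function(pixels, ext, fill) {
  means <- if (fill == "mean") {
    vapply(1:3, function(ch) mean(pixels[, , ch]), numeric(1))
  }
  for (i in seq_len(nrow(ext))) {
    if (ext$x0[i] > ext$x1[i] || ext$y0[i] > ext$y1[i]) next
    rr <- (ext$y0[i]:ext$y1[i]) + 1L
    cc <- (ext$x0[i]:ext$x1[i]) + 1L
    for (ch in 1:3) {
      pixels[rr, cc, ch] <- switch(fill,
        white = 255L,
        mean = as.integer(round(means[ch])),
        random_noise = matrix(
          as.integer(floor(runif(length(rr) * length(cc), 0, 256))),
          length(rr), length(cc))
      )
    }
  }
  pixels
}

#' Apply the Random-Cutout occlusion augmentation
#'
#' Erases `max(1, floor(N_total / n_rect_divisor))` rectangles from the
#' image: centres are sampled from the box-density probability map
#' ([build_probability_map()], [propose_centers()]), sizes from the
#' per-image bounds ([sample_rectangle_size()]), and the fill is white by
#' default. Rectangles are clipped at the borders, may overlap each other,
#' and the ground-truth boxes are returned **unchanged** — the point of the
#' augmentation is that the labels keep supervising the now-occluded ears.
#' One RNG stream per call: centres first, then sizes in centre order.
#'
#' An image with zero boxes is returned unchanged with a notice (no ears
#' means nothing whose occlusion could be simulated).
#'
#' @param image An [annotated_image()].
#' @param config A [cutout_config()].
#' @return A list of class `cutout_result`: `image` (augmented copy with
#'   identical boxes) and `rectangles`, a tibble with the centre (`x`,
#'   `y`), continuous and realised sizes, and the clipped extent
#'   (`x0`, `y0`, `x1`, `y1`; inclusive 0-based pixels).
#' @examples
#' sc <- generate_scene(scene_spec(n_ears = 8, seed = 2))
#' aug <- apply_random_cutout(sc, cutout_config(seed = 3))
#' nrow(aug$rectangles) # 8 ears -> 2 rectangles
#' @export
apply_random_cutout <- function(image, config = cutout_config()) {
  stopifnot(inherits(image, "annotated_image"),
            inherits(config, "cutout_config"))
  empty <- tibble::tibble(
    x = integer(), y = integer(), height_sampled = numeric(),
    width_sampled = numeric(), height = integer(), width = integer(),
    x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer()
  )
  n_total <- nrow(image$boxes)
  if (n_total == 0) {
    inform("image has no ears; Random-Cutout skipped")
    return(structure(list(image = image, rectangles = empty),
                     class = "cutout_result"))
  }
  local_seed(config$seed)
  n_rect <- max(1L, as.integer(floor(n_total / config$n_rect_divisor)))
  size <- dim(image$pixels)[1:2]
  map <- build_probability_map(size, image$boxes)
  centers <- propose_centers(map, n_rect)
  sizes <- sample_rectangle_size(image$boxes, config$size_divisor,
                                 n = n_rect)
  ext <- rect_extents(centers$x, centers$y, sizes$height, sizes$width, size)
  out <- image
  out$pixels <- erase_rects(image$pixels, ext, config$fill)
  rectangles <- dplyr::bind_cols(centers, sizes, ext)
  structure(list(image = out, rectangles = rectangles),
            class = "cutout_result")
}

#' @export
print.cutout_result <- function(x, ...) {
  cat(sprintf("<cutout_result> %d rectangle(s) erased from '%s'\n",
              nrow(x$rectangles), x$image$image_id))
  invisible(x)
}

#' Tidy a cutout result
#'
#' @param x A `cutout_result` from [apply_random_cutout()].
#' @param ... Unused.
#' @return The erase-rectangle table.
#' @exportS3Method generics::tidy
tidy.cutout_result <- function(x, ...) x$rectangles

#' Cutout baseline: fixed-size squares at uniform positions
#'
#' The classical Cutout augmentation: `n` axis-aligned squares of side
#' `size`, centred uniformly at random, erased to white. Ignores the
#' annotations entirely — this is the baseline whose ear-blind placement the
#' density-guided augmentation improves on.
#'
#' @param image An [annotated_image()].
#' @param n Number of squares.
#' @param size Side length in pixels.
#' @param seed Integer RNG seed.
#' @return The augmented [annotated_image()] (boxes unchanged).
#' @export
apply_cutout_baseline <- function(image, n, size, seed = NULL) {
  stopifnot(inherits(image, "annotated_image"), n >= 0, size > 0)
  local_seed(seed)
  if (n == 0) return(image)
  dims <- dim(image$pixels)[1:2]
  x <- sample.int(dims[2], n, replace = TRUE) - 1L
  y <- sample.int(dims[1], n, replace = TRUE) - 1L
  ext <- rect_extents(x, y, rep(as.integer(size), n),
                      rep(as.integer(size), n), dims)
  image$pixels <- erase_rects(image$pixels, ext, "white")
  image
}

#' Random Erasing baseline: noise-filled random rectangles
#'
#' The classical Random Erasing augmentation: `n` rectangles with side scale
#' drawn from `size_range` and aspect ratio from `aspect_range`, centred
#' uniformly at random, filled with independent uniform noise per channel.
#'
#' @param image An [annotated_image()].
#' @param n Number of rectangles.
#' @param size_range `(min, max)` characteristic side length in pixels.
#' @param aspect_range `(min, max)` height/width aspect ratio.
#' @param seed Integer RNG seed.
#' @return The augmented [annotated_image()] (boxes unchanged).
#' @export
apply_random_erasing_baseline <- function(image, n, size_range = c(8, 24),
                                          aspect_range = c(0.5, 2),
                                          seed = NULL) {
  stopifnot(inherits(image, "annotated_image"), n >= 0,
            length(size_range) == 2, all(size_range > 0),
            length(aspect_range) == 2, all(aspect_range > 0))
  local_seed(seed)
  if (n == 0) return(image)
  dims <- dim(image$pixels)[1:2]
  x <- sample.int(dims[2], n, replace = TRUE) - 1L
  y <- sample.int(dims[1], n, replace = TRUE) - 1L
  s <- runif(n, size_range[1], size_range[2])
  a <- runif(n, aspect_range[1], aspect_range[2])
  h <- pmax(1L, as.integer(round(s * sqrt(a))))
  w <- pmax(1L, as.integer(round(s / sqrt(a))))
  ext <- rect_extents(x, y, h, w, dims)
  image$pixels <- erase_rects(image$pixels, ext, "random_noise")
  image
}
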