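#' Specify a synthetic wheat ear scene
#'
#' Describes a field-of-view of a wheat canopy as rendered by
#' [generate_scene()]: a cluttered (or plain) background carrying `n_ears`
#' elliptical ear blobs at random orientations, with a controllable target
#' fraction of mutually overlapping ears. Dense mutual overlap is the norm
#' in real canopy images, so the default asks for half the ears to intersect
#' another ear.
#'
#' @param image_size Integer `(rows, cols)` canvas size in pixels.
#' @param n_ears Number of ears to place (>= 0).
#' @param ear_length_range `(min, max)` ear length (major axis) in pixels.
#' @param ear_width_range `(min, max)` ear width (minor axis) in pixels.
#' @param overlap_fraction Target fraction of ears whose bounding box
#'   intersects at least one other ear's box, in `[0, 1]`.
#' @param background `"clutter"` (textured canopy-like backdrop) or
#'   `"plain"`.
#' @param seed Integer RNG seed; the same spec and seed give bit-identical
#'   scenes.
#' @return A `scene_spec` list.
#' @examples
#' sp <- scene_spec(n_ears = 12, seed = 1)
#' sc <- generate_scene(sp)
#' sc$boxes
#' @export
scene_spec <- function(image_size = c(256, 256), n_ears = 30,
                       ear_length_range = c(24, 48),
                       ear_width_range = c(8, 16),
                       overlap_fraction = 0.5,
                       background = c("clutter", "plain"),
                       seed = 1) {
  background <- match.arg(background)
  stopifnot(
    length(image_size) == 2, all(image_size >= 1),
    n_ears >= 0,
    length(ear_length_range) == 2, all(ear_length_range > 0),
    ear_length_range[1] <= ear_length_range[2],
    length(ear_width_range) == 2, all(ear_width_range > 0),
    ear_width_range[1] <= ear_width_range[2],
    overlap_fraction >= 0, overlap_fraction <= 1
  )
  structure(
    list(image_size = as.numeric(image_size), n_ears = as.integer(n_ears),
         ear_length_range = as.numeric(ear_length_range),
         ear_width_range = as.numeric(ear_width_range),
         overlap_fraction = overlap_fraction, background = background,
         seed = seed),
    class = "scene_spec"
  )
}

# Tight axis-aligned half-extents of an ellipse with semi-axes (L/2, W/2)
# rotated by theta.
ellipse_half_extents <- function(len, wid, theta) {
  ct <- cos(theta); st <- sin(theta)
  c(hx = sqrt((len / 2 * ct)^2 + (wid / 2 * st)^2),
    hy = sqrt((len / 2 * st)^2 + (wid / 2 * ct)^2))
}

boxes_intersect <- function(x0, y0, x1, y1, bx0, by0, bx1, by1) {
  x0 < bx1 & bx0 < x1 & y0 < by1 & by0 < y1
}

# Number of ears whose box intersects at least one other (brute force).
n_overlapping <- function(g) {
  k <- nrow(g)
  if (k < 2) return(0L)
  x0 <- g$cx - g$hx; x1 <- g$cx + g$hx
  y0 <- g$cy - g$hy; y1 <- g$cy + g$hy
  hit <- logical(k)
  for (i in seq_len(k - 1)) {
    j <- (i + 1):k
    ov <- boxes_intersect(x0[i], y0[i], x1[i], y1[i],
                          x0[j], y0[j], x1[j], y1[j])
    if (any(ov)) {
      hit[i] <- TRUE
      hit[j[ov]] <- TRUE
    }
  }
  sum(hit)
}

#' Generate a synthetic annotated wheat ear scene
#'
#' Renders the scene described by a [scene_spec()]: ears are anisotropic
#' elliptical blobs with spikelet-like banding and per-pixel grain noise,
#' placed sequentially. Placement alternates adaptively between
#' "overlapping" (centred near an already placed ear) and "free" (rejection
#' sampled away from all placed ears) so that the realised fraction of
#' mutually intersecting boxes tracks `overlap_fraction`. Each ear's
#' ground-truth box is the tight axis-aligned box of its ellipse, clipped to
#' the canvas; boxes are continuous-valued pixel coordinates.
#'
#' Geometry is drawn before any pixel is rendered, so the box layout depends
#' only on the placement decisions: scaling `image_size` and both ear size
#' ranges by a power of two scales every output box by exactly that factor.
#'
#' @param spec A [scene_spec()].
#' @param render If `FALSE`, skip pixel rendering (the `pixels` array is
#'   all-zero); box geometry is unchanged. Useful for metric studies that
#'   only need annotations.
#' @return An [annotated_image()] whose `boxes` table also carries the
#'   rendering parameters (`cx`, `cy`, `len`, `wid`, `theta`) as extra
#'   columns.
#' @export
generate_scene <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  local_seed(spec$seed)
  rows <- spec$image_size[1]
  cols <- spec$image_size[2]
  geom <- place_ears(spec, rows, cols)
  pixels <- array(0L, dim = c(rows, cols, 3))
  if (render) {
    pixels <- render_background(rows, cols, spec$background)
    pixels <- render_ears(pixels, geom)
  }
  id <- sprintf("scene_%05d", as.integer(spec$seed %||% 0))
  boxes <- tibble::tibble(
    image_id = id,
    xmin = pmax(0, geom$cx - geom$hx),
    ymin = pmax(0, geom$cy - geom$hy),
    width = pmin(cols, geom$cx + geom$hx) - pmax(0, geom$cx - geom$hx),
    height = pmin(rows, geom$cy + geom$hy) - pmax(0, geom$cy - geom$hy),
    confidence = NA_real_, label = NA_character_,
    cx = geom$cx, cy = geom$cy, len = geom$len, wid = geom$wid,
    theta = geom$theta
  )
  img <- annotated_image(pixels, box_tbl(), image_id = id)
  img$boxes <- boxes
  img$spec <- spec
  img
}

place_ears <- function(spec, rows, cols) {
  n <- spec$n_ears
  g <- tibble::tibble(cx = numeric(), cy = numeric(), hx = numeric(),
                      hy = numeric(), len = numeric(), wid = numeric(),
                      theta = numeric())
  if (n == 0) return(g)
  budget <- 100 * n
  attempts <- 0
  for (k in seq_len(n)) {
    len <- runif(1, spec$ear_length_range[1], spec$ear_length_range[2])
    wid <- runif(1, spec$ear_width_range[1], spec$ear_width_range[2])
    theta <- runif(1, 0, pi)
    he <- ellipse_half_extents(len, wid, theta)
    hx <- he[["hx"]]; hy <- he[["hy"]]
    if (4 * hx * hy > rows * cols) {
      abort("blob placement infeasible: ear larger than the canvas")
    }
    want_overlap <- k > 1 &&
      n_overlapping(g) / (k - 1) < spec$overlap_fraction
    placed <- FALSE
    while (!placed) {
      attempts <- attempts + 1
      if (attempts > budget) {
        abort(sprintf(
          "blob placement infeasible: %d ears exceed the placement budget",
          n))
      }
      if (want_overlap) {
        j <- sample.int(nrow(g), 1)
        cx <- g$cx[j] + runif(1, -(hx + g$hx[j]) * 0.9, (hx + g$hx[j]) * 0.9)
        cy <- g$cy[j] + runif(1, -(hy + g$hy[j]) * 0.9, (hy + g$hy[j]) * 0.9)
        cx <- pmin(pmax(cx, 0), cols)
        cy <- pmin(pmax(cy, 0), rows)
        placed <- TRUE
      } else {
        cx <- runif(1, 0, cols)
        cy <- runif(1, 0, rows)
        clash <- nrow(g) > 0 && any(boxes_intersect(
          cx - hx, cy - hy, cx + hx, cy + hy,
          g$cx - g$hx, g$cy - g$hy, g$cx + g$hx, g$cy + g$hy))
        # dense canvases may leave no ear-free room; accept overlap rather
        # than stall (the adaptive steering compensates on later ears)
        placed <- !clash || attempts %% 50 == 0
      }
    }
    g <- dplyr::bind_rows(g, tibble::tibble(
      cx = cx, cy = cy, hx = hx, hy = hy, len = len, wid = wid,
      theta = theta))
  }
  g
}

render_background <- function(rows, cols, background) {
  px <- array(0L, dim = c(rows, cols, 3))
  if (background == "plain") {
    px[, , 1] <- 62L; px[, , 2] <- 96L; px[, , 3] <- 44L
    return(px)
  }
  # canopy-like clutter: coarse blotches + fine grain, green/brown palette
  block <- 8
  cr <- ceiling(rows / block); cc <- ceiling(cols / block)
  coarse <- matrix(runif(cr * cc), cr, cc)
  up <- kronecker(coarse, matrix(1, block, block))[seq_len(rows),
                                                   seq_len(cols)]
  grain <- matrix(runif(rows * cols, -18, 18), rows, cols)
  base <- list(r = 45 + 60 * up, g = 75 + 70 * up, b = 30 + 40 * up)
  for (ch in 1:3) {
    v <- base[[ch]] + grain
    px[, , ch] <- as.integer(pmin(255, pmax(0, round(v))))
  }
  # a few stem-like vertical streaks
  n_stems <- max(1L, (rows * cols) %/% 8192L)
  xs <- sample.int(cols, n_stems, replace = TRUE)
  for (x in xs) {
    shade <- as.integer(round(runif(1, 20, 60)))
    w <- sample(1:2, 1)
    cls <- x:min(cols, x + w - 1)
    px[, cls, 1] <- pmin(255L, px[, cls, 1, drop = FALSE] + shade)
    px[, cls, 2] <- pmin(255L, px[, cls, 2, drop = FALSE] + shade)
  }
  px
}

render_ears <- function(px, geom) {
  rows <- dim(px)[1]; cols <- dim(px)[2]
  for (i in seq_len(nrow(geom))) {
    cx <- geom$cx[i]; cy <- geom$cy[i]
    hx <- geom$hx[i]; hy <- geom$hy[i]
    c0 <- max(0L, as.integer(floor(cx - hx)))
    c1 <- min(cols - 1L, as.integer(ceiling(cx + hx)) - 1L)
    r0 <- max(0L, as.integer(floor(cy - hy)))
    r1 <- min(rows - 1L, as.integer(ceiling(cy + hy)) - 1L)
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1) + 0.5
    ys <- (r0:r1) + 0.5
    dx <- outer(ys * 0, xs - cx, `+`)
    dy <- outer(ys - cy, xs * 0, `+`)
    ct <- cos(geom$theta[i]); st <- sin(geom$theta[i])
    u <- dx * ct + dy * st        # along the major axis
    v <- -dx * st + dy * ct
    inside <- (u / (geom$len[i] / 2))^2 + (v / (geom$wid[i] / 2))^2 <= 1
    if (!any(inside)) next
    # spikelet banding along the ear plus grain noise
    band <- 0.82 + 0.18 * sin(2 * pi * u / pmax(3, geom$len[i] / 6))
    noise <- matrix(runif(length(inside), -14, 14), nrow(inside))
    base <- c(208, 182, 96)
    for (ch in 1:3) {
      plane <- px[(r0:r1) + 1L, (c0:c1) + 1L, ch, drop = TRUE]
      plane <- matrix(plane, nrow(inside), ncol(inside))
      val <- base[ch] * band + noise
      plane[inside] <- as.integer(pmin(255, pmax(0, round(val[inside]))))
      px[(r0:r1) + 1L, (c0:c1) + 1L, ch] <- plane
    }
  }
  px
}

#' Realised overlap fraction of a box set
#'
#' Fraction of boxes that intersect at least one other box, computed by
#' brute force over all pairs. This is the quantity [scene_spec()]'s
#' `overlap_fraction` targets.
#'
#' @param boxes A box table.
#' @return A scalar in `[0, 1]` (`NaN` for an empty table).
#' @export
overlap_fraction <- function(boxes) {
  n <- nrow(boxes)
  if (n == 0) return(NaN)
  if (n == 1) return(0)
  m <- iou_matrix(boxes, boxes)
  diag(m) <- 0
  mean(apply(m > 0, 1, any))
}

#' Simulate detections from ground truth
#'
#' Produces a detection set from a ground-truth scene by applying the three
#' canonical detector failure modes with known rates: missed ears (each true
#' box dropped independently with probability `miss_rate`), localisation
#' noise (each surviving edge shifted by up to `jitter` pixels), and false
#' positives (spurious boxes at ear-free locations, added at `false_rate`
#' per true box). Surviving and spurious boxes get confidences drawn
#' uniformly from `(0.5, 1]`, mirroring a detector whose acceptance
#' threshold is 0.5. Known rates make the construction parameters
#' recoverable by [count_report()].
#'
#' @param truth An [annotated_image()] or a box table.
#' @param miss_rate,false_rate Rates in `[0, 1]`.
#' @param jitter Maximum absolute per-edge perturbation in pixels.
#' @param seed Integer RNG seed.
#' @param image_size `(rows, cols)`; required when `truth` is a plain box
#'   table and `false_rate > 0`.
#' @return A detection box table sorted by descending confidence.
#' @export
generate_detections <- function(truth, miss_rate = 0, false_rate = 0,
                                jitter = 0, seed = NULL, image_size = NULL) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, false_rate >= 0, false_rate <= 1,
            jitter >= 0)
  if (inherits(truth, "annotated_image")) {
    image_size <- image_size %||% dim(truth$pixels)[1:2]
    boxes <- truth$boxes
  } else {
    boxes <- validate_boxes(truth)
  }
  local_seed(seed)
  n <- nrow(boxes)
  keep <- if (n > 0) runif(n) >= miss_rate else logical()
  dets <- boxes[keep, c("image_id", "xmin", "ymin", "width", "height"),
                drop = FALSE]
  m <- nrow(dets)
  if (m > 0 && jitter > 0) {
    e <- matrix(runif(4 * m, -jitter, jitter), m, 4)
    x1 <- dets$xmin + dets$width + e[, 2]
    y1 <- dets$ymin + dets$height + e[, 4]
    dets$xmin <- pmax(0, dets$xmin + e[, 1])
    dets$ymin <- pmax(0, dets$ymin + e[, 3])
    dets$width <- pmax(0.5, x1 - dets$xmin)
    dets$height <- pmax(0.5, y1 - dets$ymin)
  }
  dets$confidence <- if (m > 0) 1 - 0.5 * runif(m) else numeric()
  dets$label <- NA_character_
  n_fp <- if (n > 0) rbinom(1, n, false_rate) else 0L
  if (n_fp > 0) {
    if (is.null(image_size)) {
      abort("image_size is required to place false positives")
    }
    fp <- place_false_positives(boxes, n_fp, image_size)
    fp$image_id <- if (n > 0) boxes$image_id[1] else "image"
    fp$confidence <- 1 - 0.5 * runif(n_fp)
    fp$label <- NA_character_
    dets <- dplyr::bind_rows(dets, fp)
  }
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  validate_boxes(dets, require_confidence = nrow(dets) > 0)
}

place_false_positives <- function(truth, n_fp, image_size) {
  rows <- image_size[1]; cols <- image_size[2]
  w_pool <- if (nrow(truth) > 0) truth$width else rep(10, 1)
  h_pool <- if (nrow(truth) > 0) truth$height else rep(20, 1)
  out <- vector("list", n_fp)
  for (i in seq_len(n_fp)) {
    w <- w_pool[sample.int(length(w_pool), 1)]
    h <- h_pool[sample.int(length(h_pool), 1)]
    best <- NULL
    best_iou <- Inf
    for (try in 1:100) {
      cand <- tibble::tibble(
        image_id = "fp",
        xmin = runif(1, 0, max(cols - w, 0.5)),
        ymin = runif(1, 0, max(rows - h, 0.5)),
        width = min(w, cols), height = min(h, rows),
        confidence = NA_real_, label = NA_character_
      )
      worst <- if (nrow(truth) > 0) max(iou_matrix(cand, truth)) else 0
      if (worst < best_iou) {
        best <- cand
        best_iou <- worst
      }
      if (worst <= 0.05) break
    }
    out[[i]] <- best
  }
  dplyr::bind_rows(out)
}
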