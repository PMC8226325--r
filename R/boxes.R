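#' Bounding-box tables
#'
#' Axis-aligned boxes are the unit of both annotation and detection
#' throughout the package. A box table is an ordinary tibble with one row per
#' box and the columns
#'
#' * `image_id` — character image identifier,
#' * `xmin`, `ymin` — top-left corner in pixels (x = column, y = row,
#'   0-based, origin at the top-left of the image),
#' * `width`, `height` — box extent in pixels, strictly positive,
#' * `confidence` — detection score in `[0, 1]`, `NA` for ground truth,
#' * `label` — class label, `NA` when the single implicit class applies.
#'
#' Boxes live on the half-open pixel grid `[xmin, xmin + width) x
#' [ymin, ymin + height)`: a pixel with integer coordinates `(x, y)` belongs
#' to the box iff `xmin <= x < xmin + width` and `ymin <= y < ymin + height`.
#' Coordinates may be fractional (annotation files routinely store floats).
#'
#' @param xmin,ymin,width,height Numeric vectors of box geometry in pixels.
#' @param image_id Character vector (recycled) of image identifiers.
#' @param confidence Optional numeric vector of scores in `[0, 1]`.
#' @param label Optional character vector of class labels.
#'
#' @return A tibble with the columns listed above.
#' @examples
#' box_tbl(xmin = c(0, 10), ymin = c(0, 5), width = 50, height = 40)
#' @export
box_tbl <- function(xmin = numeric(), ymin = numeric(),
                    width = numeric(), height = numeric(),
                    image_id = "image", confidence = NA_real_,
                    label = NA_character_) {
  out <- tibble::tibble(
    image_id = as.character(image_id),
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    width = as.numeric(width), height = as.numeric(height),
    confidence = as.numeric(confidence), label = as.character(label)
  )
  validate_boxes(out)
}

#' Validate a box table
#'
#' Checks the box-table contract: required columns present, positive extents,
#' non-negative corners, confidences (where present) in `[0, 1]`.
#'
#' @param boxes A box table (see [box_tbl()]).
#' @param require_confidence If `TRUE`, every row must carry a confidence
#'   (detection sets require it; ground truth does not).
#' @return The validated table, invisibly unchanged, for piping.
#' @export
validate_boxes <- function(boxes, require_confidence = FALSE) {
  needed <- c("image_id", "xmin", "ymin", "width", "height")
  missing_cols <- setdiff(needed, names(boxes))
  if (length(missing_cols) > 0) {
    abort(paste0("box table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"confidence" %in% names(boxes)) boxes$confidence <- NA_real_
  if (!"label" %in% names(boxes)) boxes$label <- NA_character_
  if (nrow(boxes) > 0) {
    if (any(boxes$width <= 0) || any(boxes$height <= 0)) {
      abort("box width and height must be > 0")
    }
    if (any(boxes$xmin < 0) || any(boxes$ymin < 0)) {
      abort("box xmin and ymin must be >= 0")
    }
    conf <- boxes$confidence[!is.na(boxes$confidence)]
    if (any(conf < 0 | conf > 1)) {
      abort("confidence must lie in [0, 1]")
    }
    if (require_confidence && anyNA(boxes$confidence)) {
      abort("every detection must carry a confidence")
    }
  }
  boxes[c("image_id", "xmin", "ymin", "width", "height", "confidence", "label")]
}

#' Clip boxes to an image grid
#'
#' Boxes partially outside a `rows x cols` canvas are cut back to it; boxes
#' left with zero area (fully outside) are dropped with a warning. Clipping
#' is idempotent.
#'
#' @param boxes A box table.
#' @param image_size Integer `(rows, cols)` of the target pixel grid.
#' @return The clipped box table.
#' @examples
#' b <- box_tbl(xmin = 90, ymin = 90, width = 30, height = 30)
#' clip_boxes(b, image_size = c(100, 100))
#' @export
clip_boxes <- function(boxes, image_size) {
  stopifnot(length(image_size) == 2, all(image_size > 0))
  rows <- image_size[[1]]
  cols <- image_size[[2]]
  if (nrow(boxes) == 0) return(boxes)
  # touch only coordinates that cross a bound, so already-valid boxes pass
  # through bit-identically
  x0 <- boxes$xmin; w <- boxes$width
  left <- x0 < 0
  w[left] <- w[left] + x0[left]; x0[left] <- 0
  right <- x0 + w > cols
  w[right] <- cols - x0[right]
  y0 <- boxes$ymin; h <- boxes$height
  top <- y0 < 0
  h[top] <- h[top] + y0[top]; y0[top] <- 0
  bottom <- y0 + h > rows
  h[bottom] <- rows - y0[bottom]
  out <- boxes
  out$xmin <- x0
  out$ymin <- y0
  out$width <- w
  out$height <- h
  keep <- out$width > 0 & out$height > 0
  if (any(!keep)) {
    warn(sprintf("dropped %d box(es) with zero area after clipping",
                 sum(!keep)))
  }
  out[keep, , drop = FALSE]
}

#' Intersection-over-union of axis-aligned boxes
#'
#' IoU under the half-open pixel convention: the area of a box is
#' `width * height`, intervals `[xmin, xmin + width)` intersect like real
#' intervals. Vectorised: `a` and `b` are recycled row-wise against each
#' other. IoU is symmetric, scale-free and lies in `[0, 1]`.
#'
#' @param a,b Box tables (only the geometry columns are used).
#' @return Numeric vector of IoU values.
#' @examples
#' box_iou(box_tbl(0, 0, 2, 2), box_tbl(1, 0, 2, 2)) # 1/3
#' @export
box_iou <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (n == 0) return(numeric())
  ia <- rep_len(seq_len(max(nrow(a), 1)), n)
  ib <- rep_len(seq_len(max(nrow(b), 1)), n)
  ax0 <- a$xmin[ia]; ay0 <- a$ymin[ia]
  ax1 <- ax0 + a$width[ia]; ay1 <- ay0 + a$height[ia]
  bx0 <- b$xmin[ib]; by0 <- b$ymin[ib]
  bx1 <- bx0 + b$width[ib]; by1 <- by0 + b$height[ib]
  iw <- pmax(0, pmin(ax1, bx1) - pmax(ax0, bx0))
  ih <- pmax(0, pmin(ay1, by1) - pmax(ay0, by0))
  inter <- iw * ih
  union <- (ax1 - ax0) * (ay1 - ay0) + (bx1 - bx0) * (by1 - by0) - inter
  ifelse(union > 0, inter / union, 0)
}

# Pairwise IoU matrix between two box tables (rows of a x rows of b).
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(), nrow(a), nrow(b)))
  }
  ax0 <- a$xmin; ay0 <- a$ymin
  ax1 <- ax0 + a$width; ay1 <- ay0 + a$height
  bx0 <- b$xmin; by0 <- b$ymin
  bx1 <- bx0 + b$width; by1 <- by0 + b$height
  iw <- pmax(0, outer(ax1, bx1, pmin) - outer(ax0, bx0, pmax))
  ih <- pmax(0, outer(ay1, by1, pmin) - outer(ay0, by0, pmax))
  inter <- iw * ih
  area_a <- (ax1 - ax0) * (ay1 - ay0)
  area_b <- (bx1 - bx0) * (by1 - by0)
  union <- outer(area_a, area_b, `+`) - inter
  out <- inter / union
  out[union <= 0] <- 0
  out
}

#' Annotated images
#'
#' An annotated image couples an RGB pixel array with its ground-truth box
#' table. The pixel array is indexed `[row, col, channel]` with integer
#' values in `0..255`; pixel `(row = r, col = c)` of the array corresponds to
#' box coordinates `x = c - 1`, `y = r - 1` (0-based, origin top-left).
#'
#' @param pixels Integer array `rows x cols x 3`, values in `0..255`.
#' @param boxes A box table; clipped to the pixel grid on construction.
#' @param image_id Character scalar identifier.
#' @return An object of class `annotated_image`: a list with elements
#'   `image_id`, `pixels` and `boxes`.
#' @export
annotated_image <- function(pixels, boxes = box_tbl(), image_id = "image") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  boxes <- validate_boxes(boxes)
  boxes$image_id <- image_id
  boxes <- clip_boxes(boxes, image_size = dim(pixels)[1:2])
  structure(
    list(image_id = as.character(image_id),
         pixels = pixels, boxes = boxes),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image '%s'> %d x %d px, %d box(es)\n",
              x$image_id, d[1], d[2], nrow(x$boxes)))
  invisible(x)
}

#' @export
dim.annotated_image <- function(x) dim(x$pixels)

#' Tidy an annotated image
#'
#' @param x An [annotated_image()].
#' @param ... Unused.
#' @return The ground-truth box table.
#' @exportS3Method generics::tidy
tidy.annotated_image <- function(x, ...) x$boxes
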