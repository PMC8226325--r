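#' NMS configuration
#'
#' @param confidence_threshold Boxes with confidence strictly above this are
#'   kept (default 0.5, the detector's acceptance threshold).
#' @param iou_threshold Overlap strictly above this suppresses the
#'   lower-confidence box (default 0.5).
#' @return An `nms_config` list.
#' @export
nms_config <- function(confidence_threshold = 0.5, iou_threshold = 0.5) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            iou_threshold >= 0, iou_threshold <= 1)
  structure(list(confidence_threshold = confidence_threshold,
                 iou_threshold = iou_threshold), class = "nms_config")
}

# descending confidence, ties by larger area, then input order
confidence_order <- function(dets) {
  order(-dets$confidence, -(dets$width * dets$height),
        seq_len(nrow(dets)))
}

#' Filter detections by confidence
#'
#' Keeps boxes whose confidence is *strictly* greater than the threshold
#' ("higher than" — a box sitting exactly at the threshold is rejected) and
#' sorts the survivors by descending confidence (ties: larger area first,
#' then input order).
#'
#' @param dets A detection box table (confidence required on every row).
#' @param threshold Confidence threshold (default 0.5).
#' @return The filtered, sorted detection table.
#' @export
confidence_filter <- function(dets, threshold = 0.5) {
  dets <- validate_boxes(dets, require_confidence = TRUE)
  dets <- dets[dets$confidence > threshold, , drop = FALSE]
  dets[confidence_order(dets), , drop = FALSE]
}

#' Greedy non-maximum suppression
#'
#' An anchor-based detector emits several overlapping candidate boxes per
#' ear; NMS deletes the duplicates. Greedy descending-confidence scheme:
#' accept the most confident remaining box, delete every remaining box whose
#' IoU with it is strictly above `iou_threshold`, repeat. Confidence ties
#' break towards the larger box, then input order, so the result is
#' deterministic. NMS is idempotent and the most confident input box always
#' survives.
#'
#' @param dets A detection box table (single image, single class).
#' @param config An [nms_config()]; its `confidence_threshold` is applied
#'   first via [confidence_filter()] (set it to 0 to suppress filtering).
#' @return The surviving detections, sorted by descending confidence.
#' @examples
#' d <- box_tbl(xmin = c(0, 1), ymin = 0, width = 10, height = 10,
#'              confidence = c(0.9, 0.8))
#' nms(d, nms_config(confidence_threshold = 0)) # one box survives
#' @export
nms <- function(dets, config = nms_config()) {
  stopifnot(inherits(config, "nms_config"))
  dets <- confidence_filter(dets, config$confidence_threshold)
  n <- nrow(dets)
  if (n <= 1) return(dets)
  iou <- iou_matrix(dets, dets)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {          # rows already in priority order
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    suppress <- alive & iou[i, ] > config$iou_threshold
    alive[suppress] <- FALSE
  }
  dets[keep, , drop = FALSE]
}

#' Read and write detection results
#'
#' Detections travel either as COCO results JSON — an array of
#' `{image_id, bbox, score}` records — or as Global-Wheat-style CSV with an
#' added `score` column.
#'
#' @param path File path.
#' @param dets A detection box table.
#' @param dialect `"coco_json"` or `"gw_csv"`.
#' @param images Image roster tibble (needed for the CSV dialect's
#'   width/height columns); defaults to [annotation_images()].
#' @return `read_detections()` returns a detection box table sorted by
#'   descending confidence; the writer returns `path` invisibly.
#' @export
read_detections <- function(path, dialect = c("coco_json", "gw_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "gw_csv") {
    out <- read_annotations(path, "gw_csv")
    out <- validate_boxes(out, require_confidence = TRUE)
  } else {
    recs <- jsonlite::read_json(path)
    out <- purrr::imap_dfr(recs, function(rc, i) {
      bb <- as.numeric(unlist(rc$bbox))
      if (length(bb) != 4 || anyNA(bb) || is.null(rc$score)) {
        abort(sprintf("malformed detection record %d", i))
      }
      tibble::tibble(image_id = as.character(rc$image_id),
                     xmin = bb[1], ymin = bb[2], width = bb[3],
                     height = bb[4],
                     confidence = as.numeric(rc$score),
                     label = NA_character_)
    })
    if (nrow(out) == 0) out <- box_tbl()
  }
  out[confidence_order(out), , drop = FALSE]
}

#' @rdname read_detections
#' @export
write_detections <- function(dets, path, dialect = c("coco_json", "gw_csv"),
                             images = NULL) {
  dialect <- match.arg(dialect)
  dets <- validate_boxes(dets, require_confidence = TRUE)
  if (dialect == "gw_csv") {
    images <- images %||% annotation_images(dets)
    write_annotations(dets, path, "gw_csv", images = images)
  } else {
    recs <- purrr::map(seq_len(nrow(dets)), function(i) {
      list(image_id = dets$image_id[i],
           bbox = as.list(c(dets$xmin[i], dets$ymin[i], dets$width[i],
                            dets$height[i])),
           score = dets$confidence[i],
           category_id = 1L)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}
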