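#' Read bounding-box annotations
#'
#' Reads ground-truth (or detection) boxes from one of three dialects and
#' normalises them to the package's box-table convention: 0-based, half-open
#' `[xmin, xmin + width)`, x = column, y = row, origin top-left.
#'
#' Dialects:
#' * `gw_csv` — Global-Wheat-style CSV with columns `image_id`, `width`,
#'   `height` (image dimensions), `bbox` (a bracketed list
#'   `"[xmin, ymin, w, h]"`) and optionally `source`. One row per box;
#'   images without boxes cannot be represented in this dialect.
#' * `coco_json` — COCO detection JSON with `images`, `annotations` and
#'   `categories` arrays, `bbox = [x, y, w, h]` (already 0-based half-open).
#' * `voc_xml` — Pascal VOC XML, one file per image (pass a directory or a
#'   single file), corners `xmin/ymin/xmax/ymax` 1-based inclusive,
#'   converted on read.
#'
#' Boxes extending past the declared image bounds are clipped; boxes with
#' zero area after clipping are dropped with a warning. Confidence is left
#' `NA` for ground-truth dialects, never defaulted to 1.
#'
#' @param path File (or, for `voc_xml`, file or directory) to read.
#' @param dialect One of `"gw_csv"`, `"coco_json"`, `"voc_xml"`.
#' @param clip Clip boxes to the declared image size (default `TRUE`).
#' @return A box table (see [box_tbl()]) with additional columns
#'   `image_width` and `image_height`. The full image roster — including
#'   images that carry no boxes — is attached as the `images` attribute, a
#'   tibble retrievable with [annotation_images()].
#' @seealso [write_annotations()]
#' @export
read_annotations <- function(path, dialect = c("gw_csv", "coco_json", "voc_xml"),
                             clip = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file or directory: ", path))
  parsed <- switch(dialect,
    gw_csv = read_gw_csv(path),
    coco_json = read_coco_json(path),
    voc_xml = read_voc_xml(path)
  )
  boxes <- validate_boxes(parsed$boxes)
  boxes <- dplyr::left_join(boxes, parsed$images, by = "image_id")
  if (clip && nrow(boxes) > 0) {
    boxes <- boxes |>
      dplyr::group_split(.data$image_id) |>
      purrr::map(function(b) {
        clip_boxes(b, image_size = c(b$image_height[[1]], b$image_width[[1]]))
      }) |>
      dplyr::bind_rows()
  }
  attr(boxes, "images") <- parsed$images
  boxes
}

#' Image roster of an annotation table
#'
#' @param boxes The result of [read_annotations()].
#' @return A tibble with `image_id`, `image_width`, `image_height`, one row
#'   per declared image (including images without boxes).
#' @export
annotation_images <- function(boxes) {
  imgs <- attr(boxes, "images", exact = TRUE)
  if (is.null(imgs)) {
    imgs <- boxes |>
      dplyr::distinct(.data$image_id, .data$image_width, .data$image_height)
  }
  imgs
}

parse_bbox_cell <- function(cell, record) {
  txt <- gsub("\\[|\\]", "", cell)
  parts <- suppressWarnings(as.numeric(strsplit(txt, ",")[[1]]))
  if (length(parts) != 4 || anyNA(parts)) {
    abort(sprintf("malformed bbox cell in record %d: %s", record, cell))
  }
  parts
}

read_gw_csv <- function(path) {
  # numeric text is re-parsed with strtod (correctly rounded) so coordinates
  # and scores survive a write/read cycle bit-for-bit
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          image_id = readr::col_character(),
                          bbox = readr::col_character(),
                          .default = readr::col_character()))
  for (col in intersect(c("width", "height", "score"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  needed <- c("image_id", "width", "height", "bbox")
  if (!all(needed %in% names(df))) {
    abort(paste0("gw_csv file lacks column(s): ",
                 paste(setdiff(needed, names(df)), collapse = ", ")))
  }
  coords <- purrr::imap(df$bbox, parse_bbox_cell)
  boxes <- tibble::tibble(
    image_id = as.character(df$image_id),
    xmin = purrr::map_dbl(coords, 1), ymin = purrr::map_dbl(coords, 2),
    width = purrr::map_dbl(coords, 3), height = purrr::map_dbl(coords, 4),
    confidence = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
    label = NA_character_
  )
  images <- tibble::tibble(
    image_id = as.character(df$image_id),
    image_width = as.numeric(df$width),
    image_height = as.numeric(df$height)
  ) |> dplyr::distinct(.data$image_id, .keep_all = TRUE)
  list(boxes = boxes, images = images)
}

read_coco_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) abort(paste0("malformed COCO JSON: ", conditionMessage(e)))
  )
  if (is.null(doc$images)) abort("COCO JSON lacks an 'images' array")
  images <- purrr::map_dfr(doc$images, function(im) {
    tibble::tibble(
      coco_id = as.numeric(im$id),
      image_id = coco_image_id(im),
      image_width = as.numeric(im$width),
      image_height = as.numeric(im$height)
    )
  })
  cats <- purrr::map_dfr(doc$categories %||% list(), function(ct) {
    tibble::tibble(category_id = as.numeric(ct$id),
                   label = as.character(ct$name))
  })
  boxes <- purrr::imap_dfr(doc$annotations %||% list(), function(an, i) {
    bb <- unlist(an$bbox)
    if (length(bb) != 4 || anyNA(suppressWarnings(as.numeric(bb)))) {
      abort(sprintf("malformed bbox in COCO annotation record %d", i))
    }
    bb <- as.numeric(bb)
    tibble::tibble(
      coco_id = as.numeric(an$image_id),
      xmin = bb[1], ymin = bb[2], width = bb[3], height = bb[4],
      confidence = if (!is.null(an$score)) as.numeric(an$score) else NA_real_,
      category_id = as.numeric(an$category_id %||% NA_real_)
    )
  })
  if (nrow(boxes) == 0) {
    boxes <- tibble::tibble(coco_id = numeric(), xmin = numeric(),
                            ymin = numeric(), width = numeric(),
                            height = numeric(), confidence = numeric(),
                            category_id = numeric())
  }
  boxes <- dplyr::left_join(boxes, images[c("coco_id", "image_id")],
                            by = "coco_id")
  boxes$label <- if (nrow(cats) > 0) {
    cats$label[match(boxes$category_id, cats$category_id)]
  } else {
    NA_character_
  }
  boxes <- boxes[c("image_id", "xmin", "ymin", "width", "height",
                   "confidence", "label")]
  list(boxes = boxes, images = images[c("image_id", "image_width",
                                        "image_height")])
}

coco_image_id <- function(im) {
  fn <- im$file_name
  if (!is.null(fn)) sub("\\.[A-Za-z0-9]+$", "", as.character(fn))
  else as.character(im$id)
}

read_voc_xml <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.xml$", full.names = TRUE)
  } else {
    path
  }
  parsed <- purrr::map(files, read_voc_file)
  list(
    boxes = dplyr::bind_rows(purrr::map(parsed, "boxes")),
    images = dplyr::bind_rows(purrr::map(parsed, "image"))
  )
}

voc_num <- function(node, xp, file) {
  v <- suppressWarnings(as.numeric(xml2::xml_text(xml2::xml_find_first(node, xp))))
  if (is.na(v)) abort(sprintf("malformed VOC XML '%s': missing/invalid <%s>",
                              file, xp))
  v
}

read_voc_file <- function(file) {
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e) abort(paste0("malformed VOC XML '", file,
                                                   "': ", conditionMessage(e))))
  id <- xml2::xml_text(xml2::xml_find_first(doc, "filename"))
  id <- sub("\\.[A-Za-z0-9]+$", "", id)
  w <- voc_num(doc, "size/width", file)
  h <- voc_num(doc, "size/height", file)
  objs <- xml2::xml_find_all(doc, "object")
  boxes <- purrr::map_dfr(objs, function(ob) {
    x1 <- voc_num(ob, "bndbox/xmin", file)
    y1 <- voc_num(ob, "bndbox/ymin", file)
    x2 <- voc_num(ob, "bndbox/xmax", file)
    y2 <- voc_num(ob, "bndbox/ymax", file)
    nm <- xml2::xml_text(xml2::xml_find_first(ob, "name"))
    tibble::tibble(
      image_id = id,
      # VOC corners are 1-based inclusive; [x1, x2] covers x2 - x1 + 1 pixels.
      xmin = x1 - 1, ymin = y1 - 1,
      width = x2 - x1 + 1, height = y2 - y1 + 1,
      confidence = NA_real_,
      label = if (is.na(nm)) NA_character_ else nm
    )
  })
  list(boxes = boxes,
       image = tibble::tibble(image_id = id, image_width = w,
                              image_height = h))
}

#' Write bounding-box annotations
#'
#' Inverse of [read_annotations()]: writes a box table to the chosen dialect
#' so that reading the file back reproduces the boxes exactly (for `voc_xml`
#' coordinates are rounded to the integer pixel corners the dialect stores).
#'
#' @param boxes A box table; must carry `image_width`/`image_height` columns
#'   or an `images` attribute (both produced by [read_annotations()] and
#'   [generate_scene()]), or `images` must be supplied.
#' @param path Output file; for `voc_xml`, an output directory (one XML per
#'   image).
#' @param dialect One of `"gw_csv"`, `"coco_json"`, `"voc_xml"`.
#' @param images Optional image roster tibble (`image_id`, `image_width`,
#'   `image_height`); defaults to [annotation_images()] of `boxes`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(boxes, path,
                              dialect = c("gw_csv", "coco_json", "voc_xml"),
                              images = NULL) {
  dialect <- match.arg(dialect)
  boxes <- validate_boxes(boxes)
  images <- images %||% annotation_images(boxes)
  switch(dialect,
    gw_csv = write_gw_csv(boxes, images, path),
    coco_json = write_coco_json(boxes, images, path),
    voc_xml = write_voc_xml(boxes, images, path)
  )
  invisible(path)
}

# %.17g round-trips doubles exactly through decimal text.
fmt_g <- function(x) sprintf("%.17g", x)

write_gw_csv <- function(boxes, images, path) {
  wh <- images[match(boxes$image_id, images$image_id), ]
  df <- tibble::tibble(
    image_id = boxes$image_id,
    width = wh$image_width,
    height = wh$image_height,
    bbox = sprintf("[%s, %s, %s, %s]", fmt_g(boxes$xmin), fmt_g(boxes$ymin),
                   fmt_g(boxes$width), fmt_g(boxes$height)),
    source = "earcount"
  )
  if (any(!is.na(boxes$confidence))) df$score <- boxes$confidence
  readr::write_csv(df, path, progress = FALSE)
}

write_coco_json <- function(boxes, images, path) {
  img_list <- purrr::pmap(images, function(image_id, image_width,
                                           image_height, ...) {
    list(id = match(image_id, images$image_id),
         file_name = paste0(image_id, ".png"),
         width = image_width, height = image_height)
  })
  ann_list <- if (nrow(boxes) > 0) {
    purrr::map(seq_len(nrow(boxes)), function(i) {
      an <- list(
        id = i,
        image_id = match(boxes$image_id[i], images$image_id),
        category_id = 1L,
        bbox = as.list(c(boxes$xmin[i], boxes$ymin[i],
                         boxes$width[i], boxes$height[i])),
        area = boxes$width[i] * boxes$height[i],
        iscrowd = 0L
      )
      if (!is.na(boxes$confidence[i])) an$score <- boxes$confidence[i]
      an
    })
  } else {
    list()
  }
  doc <- list(
    images = img_list,
    annotations = ann_list,
    categories = list(list(id = 1L, name = "wheat_ear"))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
}

write_voc_xml <- function(boxes, images, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (i in seq_len(nrow(images))) {
    id <- images$image_id[i]
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", paste0(id, ".png"))
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width", fmt_g(images$image_width[i]))
    xml2::xml_add_child(size, "height", fmt_g(images$image_height[i]))
    xml2::xml_add_child(size, "depth", "3")
    b <- boxes[boxes$image_id == id, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name",
                          if (is.na(b$label[j])) "wheat_ear" else b$label[j])
      bb <- xml2::xml_add_child(ob, "bndbox")
      # back to 1-based inclusive integer corners
      xml2::xml_add_child(bb, "xmin", fmt_g(round(b$xmin[j]) + 1))
      xml2::xml_add_child(bb, "ymin", fmt_g(round(b$ymin[j]) + 1))
      xml2::xml_add_child(bb, "xmax", fmt_g(round(b$xmin[j] + b$width[j])))
      xml2::xml_add_child(bb, "ymax", fmt_g(round(b$ymin[j] + b$height[j])))
    }
    xml2::write_xml(doc, file.path(path, paste0(id, ".xml")))
  }
}
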