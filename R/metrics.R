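#' Match detections to ground truth
#'
#' Greedy one-to-one matching in descending confidence order: each detection
#' claims the unmatched truth box with which it has the highest IoU,
#' provided that IoU is at least `iou_threshold` (inclusive, unlike NMS's
#' strict threshold); otherwise it is a false detection. Each truth box is
#' matched at most once. This is the standard detection-benchmark
#' operationalisation of "counted correctly".
#'
#' @param truth A ground-truth box table (one image).
#' @param dets A detection box table (one image, confidences required).
#' @param iou_threshold Minimum IoU for a correct detection (default 0.5).
#' @return A tibble with one row per detection, in match order: `det` (input
#'   row index), `confidence`, `truth` (matched truth row index or `NA`) and
#'   `iou` (IoU with the matched box, `NA` if unmatched).
#' @export
match_detections <- function(truth, dets, iou_threshold = 0.5) {
  truth <- validate_boxes(truth)
  dets <- validate_boxes(dets, require_confidence = TRUE)
  ord <- confidence_order(dets)
  n_t <- nrow(truth)
  taken <- rep(FALSE, n_t)
  iou <- iou_matrix(dets, truth)
  out <- tibble::tibble(det = ord,
                        confidence = dets$confidence[ord],
                        truth = NA_integer_, iou = NA_real_)
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (n_t == 0 || all(taken)) break
    cand <- which(!taken)
    best <- cand[which.max(iou[i, cand])]
    if (iou[i, best] >= iou_threshold) {
      taken[best] <- TRUE
      out$truth[k] <- best
      out$iou[k] <- iou[i, best]
    }
  }
  out
}

#' Counting evaluation report
#'
#' Evaluates a counting run with the two headline criteria: counting
#' accuracy `P = N_cor / N_real` (correctly detected ears over true ears)
#' and false detection rate `O = N_err / N_num` (wrong detections over total
#' detections). `N_cor` and `N_err` partition the detections via
#' [match_detections()]; conservation holds by construction:
#' `N_cor + N_err = N_num` and `N_cor + missed = N_real`.
#'
#' With several images, `average = "pooled"` (default) sums the counts over
#' images before forming the ratios; `average = "per_image"` averages the
#' per-image ratios (images whose denominator is zero are excluded from that
#' average). Zero-denominator ratios are reported as `NA`, never as 0; the
#' `p_defined`/`o_defined` flags say which ratios exist.
#'
#' @param truth Ground-truth box table (may span several `image_id`s).
#' @param dets Detection box table (confidences required).
#' @param iou_threshold Matching IoU threshold (default 0.5, inclusive).
#' @param average `"pooled"` or `"per_image"`.
#' @return A `count_report` object; see [glance.count_report()] for the
#'   one-row summary and [tidy.count_report()] for per-image counts.
#' @examples
#' truth <- box_tbl(xmin = c(0, 20), ymin = 0, width = 10, height = 10)
#' dets <- box_tbl(xmin = c(0, 40), ymin = 0, width = 10, height = 10,
#'                 confidence = c(0.9, 0.8))
#' glance(count_report(truth, dets))
#' @export
count_report <- function(truth, dets, iou_threshold = 0.5,
                         average = c("pooled", "per_image")) {
  average <- match.arg(average)
  truth <- validate_boxes(truth)
  dets <- validate_boxes(dets, require_confidence = nrow(dets) > 0)
  ids <- union(unique(truth$image_id), unique(dets$image_id))
  per_image <- purrr::map_dfr(ids, function(id) {
    tr <- truth[truth$image_id == id, , drop = FALSE]
    dt <- dets[dets$image_id == id, , drop = FALSE]
    m <- match_detections(tr, dt, iou_threshold)
    n_cor <- sum(!is.na(m$truth))
    tibble::tibble(
      image_id = id,
      n_real = nrow(tr), n_num = nrow(dt),
      n_cor = n_cor, n_err = nrow(dt) - n_cor,
      missed = nrow(tr) - n_cor,
      p = ifelse(nrow(tr) > 0, n_cor / nrow(tr), NA_real_),
      o = ifelse(nrow(dt) > 0, (nrow(dt) - n_cor) / nrow(dt), NA_real_)
    )
  })
  if (nrow(per_image) == 0) {
    per_image <- tibble::tibble(
      image_id = character(), n_real = integer(), n_num = integer(),
      n_cor = integer(), n_err = integer(), missed = integer(),
      p = numeric(), o = numeric())
  }
  tot <- list(n_real = sum(per_image$n_real), n_num = sum(per_image$n_num),
              n_cor = sum(per_image$n_cor), n_err = sum(per_image$n_err),
              missed = sum(per_image$missed))
  if (average == "pooled") {
    p <- if (tot$n_real > 0) tot$n_cor / tot$n_real else NA_real_
    o <- if (tot$n_num > 0) tot$n_err / tot$n_num else NA_real_
    missed_rate <- if (tot$n_real > 0) tot$missed / tot$n_real else NA_real_
  } else {
    p <- if (any(!is.na(per_image$p))) mean(per_image$p, na.rm = TRUE)
         else NA_real_
    o <- if (any(!is.na(per_image$o))) mean(per_image$o, na.rm = TRUE)
         else NA_real_
    missed_rate <- if (any(!is.na(per_image$p))) 1 - p else NA_real_
  }
  structure(
    c(tot, list(p = p, o = o, missed_rate = missed_rate,
                p_defined = !is.na(p), o_defined = !is.na(o),
                average = average, iou_threshold = iou_threshold,
                per_image = per_image)),
    class = "count_report"
  )
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf("<count_report> %d image(s), %s averaging\n",
              nrow(x$per_image), x$average))
  cat(sprintf("  N_real = %d, N_num = %d, N_cor = %d, N_err = %d, missed = %d\n",
              x$n_real, x$n_num, x$n_cor, x$n_err, x$missed))
  cat(sprintf("  counting accuracy P = %s, false detection rate O = %s\n",
              if (x$p_defined) sprintf("%.4f", x$p) else "undefined",
              if (x$o_defined) sprintf("%.4f", x$o) else "undefined"))
  invisible(x)
}

#' Tidy a counting report
#'
#' @param x A [count_report()].
#' @param ... Unused.
#' @return Per-image counts and ratios, one row per image.
#' @exportS3Method generics::tidy
tidy.count_report <- function(x, ...) x$per_image

#' One-row summary of a counting report
#'
#' @param x A [count_report()].
#' @param ... Unused.
#' @return A one-row tibble with the pooled counts, `p`, `o`,
#'   `missed_rate`, the defined-ness flags and the averaging mode.
#' @exportS3Method generics::glance
glance.count_report <- function(x, ...) {
  tibble::tibble(n_real = x$n_real, n_num = x$n_num, n_cor = x$n_cor,
                 n_err = x$n_err, missed = x$missed, p = x$p, o = x$o,
                 missed_rate = x$missed_rate, p_defined = x$p_defined,
                 o_defined = x$o_defined, average = x$average,
                 iou_threshold = x$iou_threshold)
}

#' Missed-detection rate by occlusion stratum
#'
#' Real canopy images fail in characteristic ways — ear-on-ear overlap,
#' leaves covering ears, ears truncated at the frame edge. Given a
#' caller-supplied stratum label per image, reports the missed-detection
#' rate (unmatched truth boxes over truth boxes) within each stratum.
#'
#' @param truth Ground-truth box table spanning several images.
#' @param dets Detection box table for the same images.
#' @param strata A tibble with columns `image_id` and `stratum` covering
#'   every image in `truth`; an unlabelled image is an error.
#' @param iou_threshold Matching IoU threshold (default 0.5).
#' @return A tibble with one row per stratum: `stratum`, `n_images`,
#'   `n_real`, `missed`, `missed_rate` (`NA` when the stratum holds no truth
#'   boxes).
#' @export
stratified_missed_rate <- function(truth, dets, strata,
                                   iou_threshold = 0.5) {
  stopifnot(all(c("image_id", "stratum") %in% names(strata)))
  unknown <- setdiff(unique(truth$image_id), strata$image_id)
  if (length(unknown) > 0) {
    abort(paste0("no stratum label for image(s): ",
                 paste(unknown, collapse = ", ")))
  }
  rep_ <- count_report(truth, dets, iou_threshold)
  tidy(rep_) |>
    dplyr::left_join(strata[c("image_id", "stratum")], by = "image_id") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      n_real = sum(.data$n_real),
      missed = sum(.data$missed),
      missed_rate = ifelse(sum(.data$n_real) > 0,
                           sum(.data$missed) / sum(.data$n_real), NA_real_),
      .groups = "drop"
    )
}

#' Inference-speed report
#'
#' Frames per second is the reciprocal of the mean per-image inference time
#' `T`: `FPS = 1 / T`. Real-time counting conventionally requires FPS of at
#' least 24. FPS is a property of the hardware as much as of the model, so
#' this report only summarises times the caller measured.
#'
#' @param times Positive per-image wall-clock times in seconds.
#' @return A one-row tibble: `t_per_image` (mean seconds), `fps`,
#'   `n_images`.
#' @examples
#' timing_report(c(0.02, 0.06)) # T = 0.04 s -> 25 FPS
#' @export
timing_report <- function(times) {
  if (length(times) == 0) abort("no timings supplied")
  if (any(!is.finite(times) | times <= 0)) {
    abort("times must be positive and finite")
  }
  t_bar <- mean(times)
  tibble::tibble(t_per_image = t_bar, fps = 1 / t_bar,
                 n_images = length(times))
}

#' Time a per-image callable
#'
#' Convenience wrapper that runs `fn` once per element of `inputs`, measures
#' each call's wall-clock time and summarises with [timing_report()].
#'
#' @param fn A function of one argument (one image's input).
#' @param inputs A list of inputs, one per image.
#' @return A [timing_report()] tibble.
#' @export
time_inference <- function(fn, inputs) {
  times <- vapply(inputs, function(x) {
    unname(system.time(fn(x))[["elapsed"]])
  }, numeric(1))
  timing_report(pmax(times, .Machine$double.eps))
}
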