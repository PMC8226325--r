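# Independent reference implementations used to check the package's
# vectorised code paths. These deliberately use naive per-pixel / per-pair
# scalar computations so that agreement is meaningful.

# Per-pixel box-membership count evaluated directly from the formula
# I_i = 0.001 + 0.003 * n_i, pixel by pixel.
probmap_oracle <- function(image_size, boxes) {
  rows <- image_size[1]; cols <- image_size[2]
  xs <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
  ys <- matrix(rep(0:(rows - 1), times = cols), rows, cols)
  n <- matrix(0, rows, cols)
  for (i in seq_len(nrow(boxes))) {
    inside <- xs >= boxes$xmin[i] & xs < boxes$xmin[i] + boxes$width[i] &
      ys >= boxes$ymin[i] & ys < boxes$ymin[i] + boxes$height[i]
    n <- n + inside
  }
  0.001 + 0.003 * n
}

# Scalar IoU from first principles (no shared code with box_iou).
iou_scalar <- function(x0a, y0a, wa, ha, x0b, y0b, wb, hb) {
  ix <- min(x0a + wa, x0b + wb) - max(x0a, x0b)
  iy <- min(y0a + ha, y0b + hb) - max(y0a, y0b)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (wa * ha + wb * hb - inter)
}

# O(n^2) greedy NMS reference: walk boxes in priority order, re-scanning the
# accepted list pair by pair with the scalar IoU.
nms_oracle <- function(dets, conf_thr, iou_thr) {
  keep_rows <- which(dets$confidence > conf_thr)
  d <- dets[keep_rows, , drop = FALSE]
  ord <- order(-d$confidence, -(d$width * d$height), seq_len(nrow(d)))
  accepted <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      if (iou_scalar(d$xmin[i], d$ymin[i], d$width[i], d$height[i],
                     d$xmin[j], d$ymin[j], d$width[j], d$height[j]) >
          iou_thr) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  d[accepted, , drop = FALSE]
}

# Maximum-cardinality bipartite matching (augmenting paths) over the edge
# set {IoU >= threshold}; upper bound for any one-to-one matching.
max_matching_size <- function(truth, dets, iou_threshold) {
  n_d <- nrow(dets); n_t <- nrow(truth)
  if (n_d == 0 || n_t == 0) return(0L)
  edge <- matrix(FALSE, n_d, n_t)
  for (i in seq_len(n_d)) {
    for (j in seq_len(n_t)) {
      edge[i, j] <- iou_scalar(
        dets$xmin[i], dets$ymin[i], dets$width[i], dets$height[i],
        truth$xmin[j], truth$ymin[j], truth$width[j], truth$height[j]
      ) >= iou_threshold
    }
  }
  match_t <- rep(0L, n_t)
  try_augment <- function(i, visited) {
    for (j in which(edge[i, ])) {
      if (!visited[j]) {
        visited[j] <- TRUE
        if (match_t[j] == 0L ||
            Recall(match_t[j], visited)) {
          match_t[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_len(n_d)) {
    if (try_augment(i, rep(FALSE, n_t))) size <- size + 1L
  }
  size
}

# CBAM channel attention by explicit scalar loops.
channel_attention_oracle <- function(f, w) {
  d <- dim(f); n_ch <- d[3]
  avg <- numeric(n_ch); mx <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    s <- 0; m <- -Inf
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        s <- s + f[i, j, ch]
        if (f[i, j, ch] > m) m <- f[i, j, ch]
      }
    }
    avg[ch] <- s / (d[1] * d[2])
    mx[ch] <- m
  }
  mlp <- function(x) {
    hidden <- numeric(nrow(w$w0))
    for (k in seq_len(nrow(w$w0))) {
      acc <- 0
      for (c2 in seq_len(ncol(w$w0))) acc <- acc + w$w0[k, c2] * x[c2]
      hidden[k] <- max(acc, 0)
    }
    out <- numeric(nrow(w$w1))
    for (c2 in seq_len(nrow(w$w1))) {
      acc <- 0
      for (k in seq_len(ncol(w$w1))) acc <- acc + w$w1[c2, k] * hidden[k]
      out[c2] <- acc
    }
    out
  }
  z <- mlp(avg) + mlp(mx)
  1 / (1 + exp(-z))
}

# CBAM spatial attention by explicit scalar convolution loops.
spatial_attention_oracle <- function(f, w) {
  d <- dim(f)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      acc <- w$bias
      for (u in 1:7) {
        for (v in 1:7) {
          ii <- i + u - 4L; jj <- j + v - 4L
          if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
            avg <- 0; mx <- -Inf
            for (ch in seq_len(d[3])) {
              avg <- avg + f[ii, jj, ch]
              if (f[ii, jj, ch] > mx) mx <- f[ii, jj, ch]
            }
            avg <- avg / d[3]
            acc <- acc + w$kernel[u, v, 1] * avg + w$kernel[u, v, 2] * mx
          }
        }
      }
      out[i, j] <- 1 / (1 + exp(-acc))
    }
  }
  out
}

cbam_refine_oracle <- function(f, cw, sw) {
  d <- dim(f)
  mc <- channel_attention_oracle(f, cw)
  f1 <- f
  for (ch in seq_len(d[3])) f1[, , ch] <- f[, , ch] * mc[ch]
  ms <- spatial_attention_oracle(f1, sw)
  f2 <- f1
  for (ch in seq_len(d[3])) f2[, , ch] <- f1[, , ch] * ms
  f2
}

# Random integer-coordinate boxes fully inside a rows x cols grid.
random_boxes <- function(n, rows, cols, max_w = 20, max_h = 20,
                        confidence = FALSE) {
  w <- sample.int(min(max_w, cols), n, replace = TRUE)
  h <- sample.int(min(max_h, rows), n, replace = TRUE)
  x <- vapply(w, function(wi) sample.int(cols - wi + 1, 1) - 1, numeric(1))
  y <- vapply(h, function(hi) sample.int(rows - hi + 1, 1) - 1, numeric(1))
  box_tbl(xmin = x, ymin = y, width = w, height = h,
          confidence = if (confidence) runif(n, 0.01, 0.99) else NA_real_)
}

# Mask of pixels covered by the clipped erase rectangles (inclusive 0-based
# extents), built rectangle by rectangle.
rect_union_mask <- function(ext, rows, cols) {
  mask <- matrix(FALSE, rows, cols)
  for (i in seq_len(nrow(ext))) {
    if (ext$x0[i] > ext$x1[i] || ext$y0[i] > ext$y1[i]) next
    mask[(ext$y0[i]:ext$y1[i]) + 1L, (ext$x0[i]:ext$x1[i]) + 1L] <- TRUE
  }
  mask
}

# Check a cutout result against its input image: every pixel inside the
# reported rectangles is erased (white), every pixel outside is untouched.
check_erase_exact <- function(original, result) {
  d <- dim(original$pixels)
  mask <- rect_union_mask(result$rectangles, d[1], d[2])
  for (ch in 1:3) {
    plane_in <- original$pixels[, , ch]
    plane_out <- result$image$pixels[, , ch]
    if (!all(plane_out[mask] == 255L)) return(FALSE)
    if (!all(plane_out[!mask] == plane_in[!mask])) return(FALSE)
  }
  TRUE
}

# Byte-level fingerprints of every file under a directory (relative order).
dir_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) {
    paste(as.character(readBin(f, "raw", file.size(f))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
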