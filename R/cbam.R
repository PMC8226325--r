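#' Weights for the CBAM shared channel MLP
#'
#' The channel-attention branch passes both pooled channel descriptors
#' through one shared two-layer perceptron with a bottleneck of size `C/r`
#' and a ReLU between the layers (no bias terms). `w0` compresses
#' `C -> C/r`, `w1` expands `C/r -> C`.
#'
#' @param w0 Numeric matrix `C/r x C`.
#' @param w1 Numeric matrix `C x C/r`.
#' @return A `channel_mlp_weights` list with `w0`, `w1` and the inferred
#'   reduction ratio `r`.
#' @export
channel_mlp_weights <- function(w0, w1) {
  w0 <- as.matrix(w0); w1 <- as.matrix(w1)
  c_full <- ncol(w0); c_red <- nrow(w0)
  if (nrow(w1) != c_full || ncol(w1) != c_red) {
    abort(sprintf(
      "w1 must be %d x %d to invert w0's %d x %d compression",
      c_full, c_red, c_red, c_full))
  }
  if (c_full %% c_red != 0) {
    abort("number of channels must be divisible by the reduction ratio")
  }
  structure(list(w0 = w0, w1 = w1, r = c_full %/% c_red),
            class = "channel_mlp_weights")
}

#' Random CBAM weights (for testing and demos)
#'
#' @param channels Number of channels `C`.
#' @param r Reduction ratio (default 16; must divide `C`).
#' @param seed Integer RNG seed.
#' @param sd Standard deviation of the normal draws.
#' @return A list with `channel` ([channel_mlp_weights()]) and `spatial`
#'   ([spatial_conv_weights()]).
#' @export
random_cbam_weights <- function(channels, r = 16, seed = NULL, sd = 0.5) {
  if (channels %% r != 0) abort("channels must be divisible by r")
  local_seed(seed)
  cr <- channels %/% r
  list(
    channel = channel_mlp_weights(
      w0 = matrix(stats::rnorm(cr * channels, sd = sd), cr, channels),
      w1 = matrix(stats::rnorm(channels * cr, sd = sd), channels, cr)
    ),
    spatial = spatial_conv_weights(
      kernel = array(stats::rnorm(7 * 7 * 2, sd = sd), dim = c(7, 7, 2))
    )
  )
}

#' Weights for the CBAM spatial convolution
#'
#' @param kernel Numeric array `7 x 7 x 2` applied (as cross-correlation)
#'   over the stacked average- and max-pooled spatial descriptors, in that
#'   order.
#' @param bias Scalar bias (default 0).
#' @return A `spatial_conv_weights` list.
#' @export
spatial_conv_weights <- function(kernel, bias = 0) {
  kernel <- array(kernel, dim = dim(kernel) %||% c(7, 7, 2))
  if (!identical(dim(kernel), c(7L, 7L, 2L))) {
    abort("kernel must be a 7 x 7 x 2 array")
  }
  stopifnot(length(bias) == 1, is.finite(bias))
  structure(list(kernel = kernel, bias = as.numeric(bias)),
            class = "spatial_conv_weights")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

check_feature_map <- function(f) {
  if (length(dim(f)) != 3) abort("feature map must be a 3-D (W, H, C) array")
  if (!all(is.finite(f))) abort("feature map must be finite")
  invisible(f)
}

#' CBAM channel attention
#'
#' Computes `M_c = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))`: each channel
#' is summarised by its global average and global maximum over spatial
#' positions; both descriptors pass through the *shared* bottleneck MLP
#' (`w1 %*% relu(w0 %*% x)`); the two outputs are summed element-wise and
#' squashed by the logistic sigmoid. The sum makes the two descriptors
#' interchangeable: swapping them leaves `M_c` unchanged.
#'
#' @param f A 3-D feature array indexed `(W, H, C)`.
#' @param weights A [channel_mlp_weights()] with `C` matching `f`.
#' @return Numeric vector of length `C` with entries strictly in `(0, 1)`.
#' @export
channel_attention <- function(f, weights) {
  check_feature_map(f)
  stopifnot(inherits(weights, "channel_mlp_weights"))
  ch <- dim(f)[3]
  if (ncol(weights$w0) != ch) {
    abort(sprintf("feature map has %d channels but w0 expects %d",
                  ch, ncol(weights$w0)))
  }
  f_avg <- apply(f, 3, mean)
  f_max <- apply(f, 3, max)
  mlp <- function(x) as.vector(weights$w1 %*% pmax(weights$w0 %*% x, 0))
  as.vector(sigmoid(mlp(f_avg) + mlp(f_max)))
}

#' CBAM spatial attention
#'
#' Computes `M_s = sigmoid(f7x7([AvgPool(F); MaxPool(F)]))`: each spatial
#' position is summarised by its mean and maximum across channels; the two
#' descriptor maps are stacked and convolved with a 7 x 7 kernel under
#' same-size zero padding, then squashed by the sigmoid. Zero padding keeps
#' the output multiplicable with the input feature map.
#'
#' @param f A 3-D feature array indexed `(W, H, C)`.
#' @param weights A [spatial_conv_weights()].
#' @return Numeric `W x H` matrix with entries strictly in `(0, 1)`.
#' @export
spatial_attention <- function(f, weights) {
  check_feature_map(f)
  stopifnot(inherits(weights, "spatial_conv_weights"))
  d <- dim(f)
  avg <- apply(f, c(1, 2), mean)
  mx <- apply(f, c(1, 2), max)
  avg <- matrix(avg, d[1], d[2])
  mx <- matrix(mx, d[1], d[2])
  acc <- matrix(weights$bias, d[1], d[2])
  for (u in 1:7) {
    for (v in 1:7) {
      du <- u - 4L; dv <- v - 4L
      shifted_a <- shift_zero(avg, du, dv)
      shifted_m <- shift_zero(mx, du, dv)
      acc <- acc + weights$kernel[u, v, 1] * shifted_a +
        weights$kernel[u, v, 2] * shifted_m
    }
  }
  sigmoid(acc)
}

# m shifted so that out[i, j] = m[i + di, j + dj], zero outside.
shift_zero <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  lo_i <- max(1, 1 + di); hi_i <- min(nr, nr + di)
  lo_j <- max(1, 1 + dj); hi_j <- min(nc, nc + dj)
  if (lo_i > hi_i || lo_j > hi_j) return(out)
  ri <- lo_i:hi_i; rj <- lo_j:hi_j
  out[ri - di, rj - dj] <- m[ri, rj]
  out
}

#' Refine a feature map with CBAM
#'
#' Two sequential multiplicative gatings: first the channel attention vector
#' is broadcast over spatial positions (`F1 = M_c(F) * F`), then the spatial
#' attention of the refined map is broadcast over channels
#' (`F2 = M_s(F1) * F1`). Both gains lie in `(0, 1)`, so for non-negative
#' input the refinement is an element-wise contraction.
#'
#' @param f A 3-D feature array indexed `(W, H, C)`.
#' @param channel_weights A [channel_mlp_weights()].
#' @param spatial_weights A [spatial_conv_weights()].
#' @return A list of class `cbam_result`: `refined` (array, same shape as
#'   `f`), `channel_attention` (length-`C` vector) and `spatial_attention`
#'   (`W x H` matrix, computed on the channel-refined map).
#' @export
cbam_refine <- function(f, channel_weights, spatial_weights) {
  check_feature_map(f)
  mc <- channel_attention(f, channel_weights)
  d <- dim(f)
  f1 <- f * rep(mc, each = d[1] * d[2])
  ms <- spatial_attention(f1, spatial_weights)
  f2 <- f1 * as.vector(ms)
  structure(list(refined = f2, channel_attention = mc,
                 spatial_attention = ms),
            class = "cbam_result")
}

#' @export
print.cbam_result <- function(x, ...) {
  d <- dim(x$refined)
  cat(sprintf("<cbam_result> %d x %d x %d feature map refined\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Read or write CBAM weights as a portable archive
#'
#' Weights travel as a flat JSON object holding the numeric arrays and their
#' dimensions — no framework checkpoint formats.
#'
#' @param weights A list with `channel` and `spatial` components, as from
#'   [random_cbam_weights()].
#' @param path File path.
#' @return `read_cbam_weights()` returns the weights list; the writer
#'   returns `path` invisibly.
#' @export
write_cbam_weights <- function(weights, path) {
  obj <- list(
    w0 = list(dim = dim(weights$channel$w0),
              data = as.vector(weights$channel$w0)),
    w1 = list(dim = dim(weights$channel$w1),
              data = as.vector(weights$channel$w1)),
    kernel = list(dim = dim(weights$spatial$kernel),
                  data = as.vector(weights$spatial$kernel)),
    bias = weights$spatial$bias
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cbam_weights
#' @export
read_cbam_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    channel = channel_mlp_weights(
      w0 = matrix(obj$w0$data, obj$w0$dim[1], obj$w0$dim[2]),
      w1 = matrix(obj$w1$data, obj$w1$dim[1], obj$w1$dim[2])
    ),
    spatial = spatial_conv_weights(
      kernel = array(obj$kernel$data, dim = obj$kernel$dim),
      bias = obj$bias
    )
  )
}
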