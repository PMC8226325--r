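test_that("a zero-ear spec yields an image with an empty box list", {
  sc <- generate_scene(scene_spec(image_size = c(32, 32), n_ears = 0,
                                  seed = 1))
  expect_s3_class(sc, "annotated_image")
  expect_equal(nrow(sc$boxes), 0)
})

test_that("identical spec and seed give bit-identical scenes", {
  sp <- scene_spec(image_size = c(96, 96), n_ears = 30,
                   ear_length_range = c(10, 20), ear_width_range = c(4, 8),
                   seed = 1)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$boxes, b$boxes)
})

test_that("realised overlap fraction tracks the requested target", {
  sc <- generate_scene(scene_spec(
    image_size = c(320, 320), n_ears = 50, overlap_fraction = 0.6,
    seed = 7), render = FALSE)
  f <- overlap_fraction(sc$boxes)
  expect_gte(f, 0.45)
  expect_lte(f, 0.75)
  # brute-force cross-check of the overlap measurement itself
  hits <- vapply(seq_len(50), function(i) {
    any(vapply(setdiff(seq_len(50), i), function(j) {
      iou_scalar(sc$boxes$xmin[i], sc$boxes$ymin[i], sc$boxes$width[i],
                 sc$boxes$height[i], sc$boxes$xmin[j], sc$boxes$ymin[j],
                 sc$boxes$width[j], sc$boxes$height[j]) > 0
    }, logical(1)))
  }, logical(1))
  expect_equal(f, mean(hits))
})

test_that("every box contains its blob's rendered pixel support", {
  sc <- generate_scene(scene_spec(image_size = c(128, 128), n_ears = 15,
                                  overlap_fraction = 0, seed = 5,
                                  background = "plain"))
  # ear pixels are golden: red channel well above the plain background's 62
  for (i in seq_len(nrow(sc$boxes))) {
    b <- sc$boxes[i, ]
    ct <- cos(b$theta); st <- sin(b$theta)
    support <- which(sc$pixels[, , 1] > 130, arr.ind = TRUE)
    xs <- support[, 2] - 1 + 0.5
    ys <- support[, 1] - 1 + 0.5
    u <- (xs - b$cx) * ct + (ys - b$cy) * st
    v <- -(xs - b$cx) * st + (ys - b$cy) * ct
    mine <- (u / (b$len / 2))^2 + (v / (b$wid / 2))^2 <= 1
    if (!any(mine)) next
    expect_gte(min(xs[mine]), b$xmin)
    expect_lte(max(xs[mine]), b$xmin + b$width)
    expect_gte(min(ys[mine]), b$ymin)
    expect_lte(max(ys[mine]), b$ymin + b$height)
  }
})

test_that("doubling the canvas and ear sizes doubles every box exactly", {
  base <- generate_scene(scene_spec(
    image_size = c(96, 96), n_ears = 25, ear_length_range = c(12, 24),
    ear_width_range = c(4, 8), overlap_fraction = 0.5, seed = 3),
    render = FALSE)$boxes
  scaled <- generate_scene(scene_spec(
    image_size = c(192, 192), n_ears = 25, ear_length_range = c(24, 48),
    ear_width_range = c(8, 16), overlap_fraction = 0.5, seed = 3),
    render = FALSE)$boxes
  expect_identical(base$xmin * 2, scaled$xmin)
  expect_identical(base$ymin * 2, scaled$ymin)
  expect_identical(base$width * 2, scaled$width)
  expect_identical(base$height * 2, scaled$height)
})

test_that("infeasible placement requests fail with a generation error", {
  expect_error(
    generate_scene(scene_spec(image_size = c(8, 8), n_ears = 3,
                              ear_length_range = c(30, 40),
                              ear_width_range = c(20, 30), seed = 1)),
    "infeasible")
})

test_that("noise-free detections reproduce the truth exactly", {
  sc <- generate_scene(scene_spec(image_size = c(96, 96), n_ears = 12,
                                  seed = 2), render = FALSE)
  d <- generate_detections(sc, miss_rate = 0, false_rate = 0, jitter = 0,
                           seed = 9)
  expect_equal(nrow(d), 12)
  ord <- order(d$xmin, d$ymin)
  ref <- order(sc$boxes$xmin, sc$boxes$ymin)
  expect_identical(d$xmin[ord], sc$boxes$xmin[ref])
  expect_identical(d$width[ord], sc$boxes$width[ref])
  expect_true(all(d$confidence > 0.5 & d$confidence <= 1))
  expect_true(all(diff(d$confidence) <= 0))   # sorted descending
})

test_that("total miss rate with no false positives empties the detections", {
  sc <- generate_scene(scene_spec(image_size = c(64, 64), n_ears = 8,
                                  seed = 3), render = FALSE)
  d <- generate_detections(sc, miss_rate = 1, false_rate = 0, seed = 1)
  expect_equal(nrow(d), 0)
})

test_that("survivor counts follow the binomial thinning they are drawn from", {
  sc <- generate_scene(scene_spec(image_size = c(512, 512), n_ears = 100,
                                  overlap_fraction = 0.3, seed = 11),
                       render = FALSE)
  n_runs <- 200
  survivors <- vapply(seq_len(n_runs), function(s) {
    nrow(generate_detections(sc, miss_rate = 0.1, seed = s))
  }, numeric(1))
  # direct binomial resampling oracle under the same law
  withr::local_seed(1)
  oracle <- rbinom(n_runs, 100, 0.9)
  se <- sqrt(100 * 0.1 * 0.9 / n_runs)
  expect_lt(abs(mean(survivors) - mean(oracle)), 4 * se)
  expect_true(all(survivors <= 100))
})

test_that("false positives avoid the true ears and carry confidences", {
  sc <- generate_scene(scene_spec(image_size = c(256, 256), n_ears = 20,
                                  overlap_fraction = 0.2, seed = 4),
                       render = FALSE)
  d <- generate_detections(sc, miss_rate = 1, false_rate = 0.5, seed = 5)
  expect_gt(nrow(d), 0)
  m <- max(box_iou(d[rep(seq_len(nrow(d)), each = 20), ],
                   sc$boxes[rep(1:20, nrow(d)), ]))
  expect_lt(m, 0.5)
  expect_true(all(d$confidence > 0.5))
})
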