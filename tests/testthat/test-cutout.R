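make_scene <- function(n_ears, seed, size = 96) {
  generate_scene(scene_spec(image_size = c(size, size), n_ears = n_ears,
                            ear_length_range = c(12, 24),
                            ear_width_range = c(4, 8), seed = seed))
}

test_that("centre sampling follows the normalised map", {
  expect_equal(nrow(propose_centers(build_probability_map(c(8, 8),
                                                          box_tbl()), 0)),
               0)
  # uniform map, n = all pixels: every pixel exactly once
  ctr <- propose_centers(build_probability_map(c(6, 7), box_tbl()), 42,
                         seed = 1)
  expect_equal(nrow(dplyr::distinct(ctr)), 42)
  expect_error(propose_centers(build_probability_map(c(4, 4), box_tbl()),
                               17), "more centres")
  # a box-covered region is hit with its normalised mass
  boxes <- box_tbl(xmin = 4, ymin = 4, width = 8, height = 8)
  m <- build_probability_map(c(16, 16), boxes)
  p_in <- 64 * 0.004 / (64 * 0.004 + (256 - 64) * 0.001)
  withr::local_seed(10)
  hits <- vapply(seq_len(4000), function(i) {
    ctr <- propose_centers(m, 1)
    ctr$x >= 4 && ctr$x < 12 && ctr$y >= 4 && ctr$y < 12
  }, logical(1))
  se <- sqrt(p_in * (1 - p_in) / 4000)
  expect_lt(abs(mean(hits) - p_in), 3 * se)
})

test_that("rectangle sizes are uniform on the quarter-size interval", {
  # identical boxes degenerate to a point mass at size/4
  b <- box_tbl(xmin = c(0, 30), ymin = c(0, 30), width = 20, height = 40)
  s <- sample_rectangle_size(b, n = 50, seed = 1)
  expect_true(all(s$height == 10))
  expect_true(all(s$width == 5))
  # heights {20, 60} -> H uniform on [5, 15], mean 10
  b2 <- box_tbl(xmin = c(0, 30), ymin = c(0, 30), width = c(10, 10),
                height = c(20, 60))
  s2 <- sample_rectangle_size(b2, n = 10000, seed = 2)
  expect_true(all(s2$height_sampled >= 5 & s2$height_sampled <= 15))
  expect_lt(abs(mean(s2$height_sampled) - 10), 0.2)
  # a 4x4 ear floors both dimensions at 1 pixel
  s3 <- sample_rectangle_size(box_tbl(0, 0, 4, 4), n = 20, seed = 3)
  expect_true(all(s3$height == 1L & s3$width == 1L))
  expect_error(sample_rectangle_size(box_tbl()), "no boxes")
})

test_that("the rectangle-count law is max(1, floor(N_total / 4))", {
  for (case in list(c(8, 2), c(3, 1), c(4, 1), c(7, 1), c(12, 3),
                    c(17, 4))) {
    sc <- make_scene(case[1], seed = case[1])
    aug <- apply_random_cutout(sc, cutout_config(seed = 1))
    expect_equal(nrow(aug$rectangles), case[2])
  }
})

test_that("boxes pass through the augmentation untouched", {
  sc <- make_scene(10, seed = 21)
  aug <- apply_random_cutout(sc, cutout_config(seed = 2))
  expect_identical(aug$image$boxes, sc$boxes)
  expect_identical(aug$image$image_id, sc$image_id)
})

test_that("erased pixels are exactly the reported rectangles", {
  for (seed in 1:5) {
    sc <- make_scene(9, seed = seed)
    aug <- apply_random_cutout(sc, cutout_config(seed = seed + 100))
    expect_true(check_erase_exact(sc, aug))
  }
})

test_that("sampled sizes respect the per-image quarter bounds", {
  sc <- make_scene(16, seed = 33)
  h_rng <- range(sc$boxes$height) / 4
  w_rng <- range(sc$boxes$width) / 4
  aug <- apply_random_cutout(sc, cutout_config(seed = 9))
  expect_true(all(aug$rectangles$height_sampled >= h_rng[1] &
                    aug$rectangles$height_sampled <= h_rng[2]))
  expect_true(all(aug$rectangles$width_sampled >= w_rng[1] &
                    aug$rectangles$width_sampled <= w_rng[2]))
})

test_that("an ear-free image is returned unchanged with a notice", {
  img <- annotated_image(array(7L, dim = c(16, 16, 3)), box_tbl())
  expect_message(res <- apply_random_cutout(img, cutout_config(seed = 1)),
                 "skipped")
  expect_identical(res$image$pixels, img$pixels)
  expect_equal(nrow(res$rectangles), 0)
})

test_that("augmentation is reproducible under a fixed seed", {
  sc <- make_scene(10, seed = 5)
  a <- apply_random_cutout(sc, cutout_config(seed = 77))
  b <- apply_random_cutout(sc, cutout_config(seed = 77))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$rectangles, b$rectangles)
})

test_that("erasures concentrate where ears are dense", {
  # ears packed into the top-left quadrant; background elsewhere
  sp <- scene_spec(image_size = c(80, 80), n_ears = 0, seed = 1)
  sc <- generate_scene(sp)
  withr::local_seed(6)
  sc$boxes <- box_tbl(xmin = runif(15, 0, 25), ymin = runif(15, 0, 25),
                      width = 12, height = 12)
  freq <- matrix(0, 80, 80)
  for (s in 1:150) {
    aug <- apply_random_cutout(sc, cutout_config(seed = s))
    freq <- freq + rect_union_mask(aug$rectangles, 80, 80)
  }
  in_cluster <- mean(freq[1:38, 1:38])
  outside <- mean(freq[41:80, 41:80])
  expect_gt(in_cluster, outside)
})

test_that("default erasures rarely blot out a whole ear", {
  sc <- generate_scene(scene_spec(image_size = c(128, 128), n_ears = 24,
                                  seed = 9))
  n_trials <- 150
  covered <- 0L
  total <- 0L
  for (s in seq_len(n_trials)) {
    aug <- apply_random_cutout(sc, cutout_config(seed = s))
    mask <- rect_union_mask(aug$rectangles, 128, 128)
    for (i in seq_len(nrow(sc$boxes))) {
      b <- sc$boxes[i, ]
      cc <- (max(0, ceiling(b$xmin)):min(127, ceiling(b$xmin + b$width) - 1)) + 1
      rr <- (max(0, ceiling(b$ymin)):min(127, ceiling(b$ymin + b$height) - 1)) + 1
      total <- total + 1L
      if (mean(mask[rr, cc]) >= 0.95) covered <- covered + 1L
    }
  }
  expect_lt(covered / total, 0.05)
})

test_that("the fixed-size cutout baseline erases white squares anywhere", {
  img <- make_scene(5, seed = 12)
  expect_identical(apply_cutout_baseline(img, 0, 10, seed = 1)$pixels,
                   img$pixels)
  whole <- apply_cutout_baseline(img, 1, 2 * 96, seed = 1)
  expect_true(all(whole$pixels == 255L))
  part <- apply_cutout_baseline(img, 3, 12, seed = 4)
  changed <- sum(part$pixels != img$pixels) / 3
  expect_lte(changed, 3 * 12^2)
  expect_identical(part$boxes, img$boxes)
})

test_that("random erasing fills with uniform noise and is reproducible", {
  img <- make_scene(5, seed = 13)
  expect_identical(
    apply_random_erasing_baseline(img, 0, seed = 1)$pixels, img$pixels)
  a <- apply_random_erasing_baseline(img, 6, size_range = c(20, 40),
                                     seed = 3)
  b <- apply_random_erasing_baseline(img, 6, size_range = c(20, 40),
                                     seed = 3)
  expect_identical(a$pixels, b$pixels)
  noise <- a$pixels[a$pixels != img$pixels]
  expect_gt(length(noise), 1e4)
  expect_lt(abs(mean(noise) - 127.5), 3)
})
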