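test_that("perfect detections match one-to-one with no errors", {
  withr::local_seed(1)
  truth <- random_boxes(15, 100, 100)
  dets <- truth
  dets$confidence <- runif(15, 0.6, 1)
  m <- match_detections(truth, dets)
  expect_true(all(!is.na(m$truth)))
  expect_equal(sort(m$truth), 1:15)
  g <- glance(count_report(truth, dets))
  expect_equal(g$n_cor, 15)
  expect_equal(g$n_err, 0)
  expect_equal(g$p, 1)
  expect_equal(g$o, 0)
})

test_that("empty detections leave everything missed, ratios undefined where due", {
  withr::local_seed(2)
  truth <- random_boxes(10, 50, 50)
  g <- glance(count_report(truth, box_tbl()))
  expect_equal(g$n_cor, 0)
  expect_equal(g$n_err, 0)
  expect_equal(g$missed, 10)
  expect_equal(g$p, 0)
  expect_true(is.na(g$o))       # no detections: O undefined, not 0
  expect_false(g$o_defined)
  # no truth either: P undefined too
  g2 <- glance(count_report(box_tbl(), box_tbl()))
  expect_true(is.na(g2$p) && is.na(g2$o))
})

test_that("report arithmetic follows the P and O definitions", {
  # 50 true ears, 47 found correctly, 3 false detections
  truth <- box_tbl(xmin = seq(0, 49) * 30, ymin = 0, width = 20,
                   height = 20)
  dets <- truth[1:47, ]
  dets$confidence <- 0.9
  fps <- box_tbl(xmin = seq(0, 2) * 30 + 1500, ymin = 200, width = 20,
                 height = 20, confidence = 0.8)
  g <- glance(count_report(truth, dplyr::bind_rows(dets, fps)))
  expect_equal(g$p, 47 / 50)     # P = N_cor / N_real = 0.94
  expect_equal(g$o, 3 / 50)      # O = N_err / N_num = 0.06
  expect_equal(g$n_num, 50)
})

test_that("conservation identities hold across random evaluations", {
  for (seed in 1:10) {
    sc <- generate_scene(scene_spec(image_size = c(256, 256), n_ears = 40,
                                    seed = seed), render = FALSE)
    d <- generate_detections(sc, miss_rate = 0.2, false_rate = 0.1,
                             jitter = 1, seed = seed + 50)
    g <- glance(count_report(sc$boxes, d))
    expect_identical(g$n_cor + g$n_err, g$n_num)
    expect_identical(g$n_cor + g$missed, g$n_real)
  }
})

test_that("greedy matching attains the maximum matching on jittered scenes", {
  for (seed in 1:8) {
    sc <- generate_scene(scene_spec(image_size = c(256, 256), n_ears = 18,
                                    seed = seed), render = FALSE)
    d <- generate_detections(sc, miss_rate = 0.1, jitter = 1,
                             seed = seed + 10)
    m <- match_detections(sc$boxes, d, 0.5)
    expect_equal(sum(!is.na(m$truth)),
                 max_matching_size(sc$boxes, d, 0.5))
  }
})

test_that("detection order at equal confidence does not change the report", {
  withr::local_seed(3)
  truth <- random_boxes(12, 80, 80)
  dets <- truth
  dets$confidence <- 0.8
  dets2 <- dets[sample.int(12), ]
  g1 <- glance(count_report(truth, dets))
  g2 <- glance(count_report(truth, dets2))
  expect_equal(g1[c("n_cor", "n_err", "p", "o")],
               g2[c("n_cor", "n_err", "p", "o")])
})

test_that("P and O are invariant to uniform coordinate rescaling", {
  withr::local_seed(4)
  truth <- random_boxes(10, 64, 64)
  dets <- generate_detections(truth, miss_rate = 0.2, jitter = 0.5,
                              seed = 5)
  scale_boxes <- function(b, k) {
    b$xmin <- b$xmin * k; b$ymin <- b$ymin * k
    b$width <- b$width * k; b$height <- b$height * k
    b
  }
  g1 <- glance(count_report(truth, dets))
  g2 <- glance(count_report(scale_boxes(truth, 8), scale_boxes(dets, 8)))
  expect_equal(g1$p, g2$p)
  expect_equal(g1$o, g2$o)
})

test_that("averaging modes pool or average as documented", {
  truth <- dplyr::bind_rows(
    box_tbl(xmin = c(0, 30), ymin = 0, width = 10, height = 10,
            image_id = "a"),
    box_tbl(xmin = c(0, 30, 60, 90), ymin = 0, width = 10, height = 10,
            image_id = "b"))
  dets <- dplyr::bind_rows(
    box_tbl(0, 0, 10, 10, image_id = "a", confidence = 0.9),
    box_tbl(xmin = c(0, 30, 60, 90), ymin = 0, width = 10, height = 10,
            image_id = "b", confidence = 0.9))
  pooled <- glance(count_report(truth, dets, average = "pooled"))
  per_im <- glance(count_report(truth, dets, average = "per_image"))
  expect_equal(pooled$p, 5 / 6)
  expect_equal(per_im$p, (0.5 + 1) / 2)
})

test_that("stratified missed rates recover their construction values", {
  n_img <- 30
  scenes <- purrr::map(seq_len(n_img), function(i) {
    generate_scene(scene_spec(image_size = c(192, 192), n_ears = 20,
                              seed = 300 + i), render = FALSE)
  })
  strata <- tibble::tibble(
    image_id = purrr::map_chr(scenes, "image_id"),
    stratum = rep(c("overlap", "leaf"), each = n_img / 2))
  rates <- c(overlap = 0.3, leaf = 0.1)
  dets <- purrr::imap_dfr(scenes, function(sc, i) {
    generate_detections(sc, miss_rate = rates[[strata$stratum[i]]],
                        jitter = 0.5, seed = 600 + i)
  })
  truth <- dplyr::bind_rows(purrr::map(scenes, "boxes"))
  out <- stratified_missed_rate(truth, dets, strata)
  for (s in names(rates)) {
    n <- 20 * n_img / 2
    se <- sqrt(rates[[s]] * (1 - rates[[s]]) / n)
    got <- out$missed_rate[out$stratum == s]
    expect_lt(abs(got - rates[[s]]), 3 * se)
  }
  # unlabelled image is an argument error
  expect_error(stratified_missed_rate(truth, dets, strata[-1, ]),
               "no stratum label")
  # empty stratum: undefined, not zero
  strata2 <- strata
  strata2$stratum[1] <- "edge"
  sub <- truth[truth$image_id != strata$image_id[1], ]
  out2 <- stratified_missed_rate(sub, dets, strata2)
  expect_true(is.na(out2$missed_rate[out2$stratum == "edge"]))
})

test_that("timing reports take the mean then the reciprocal", {
  t1 <- timing_report(rep(0.04, 10))
  expect_equal(t1$fps, 25)
  t2 <- timing_report(c(0.02, 0.06))
  expect_equal(t2$t_per_image, 0.04)
  expect_equal(t2$fps, 25)
  withr::local_seed(6)
  times <- runif(100, 0.01, 0.2)
  t3 <- timing_report(times)
  acc <- 0
  for (x in times) acc <- acc + x
  expect_equal(t3$t_per_image, acc / 100)
  expect_equal(t3$fps, 100 / acc)
  expect_error(timing_report(numeric()), "no timings")
  expect_error(timing_report(c(0.1, -1)), "positive")
  # measured callables produce a positive rate
  tr <- time_inference(function(x) sum(sqrt(seq_len(2e4))), as.list(1:3))
  expect_gt(tr$fps, 0)
  expect_equal(tr$n_images, 3)
})
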