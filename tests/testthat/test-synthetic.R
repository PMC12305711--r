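test_that("class sampling follows the long-tail priors", {
  expect_equal(sample_icdas_classes(50, c(1, rep(0, 6))), rep(0L, 50))
  x1 <- sample_icdas_classes(100, seed = 99)
  x2 <- sample_icdas_classes(100, seed = 99)
  expect_identical(x1, x2)
  # law of large numbers against the normalized instance counts
  x <- sample_icdas_classes(60000, seed = 100)
  expect_equal(mean(x == 1), 21102 / 61280, tolerance = 0.01 / 0.344)
  expect_lt(mean(x == 6), 0.02)
  expect_error(sample_icdas_classes(10, priors = rep(0.2, 5)),
               class = "dentpost_schema_error")
})

test_that("the zero-jitter arch is near-equidistant with interior angles above 90", {
  p <- scene_params(jitter = 0)
  g <- generate_arch(p, seed = 1)
  expect_equal(nrow(g), 14)
  gaps <- sqrt(diff(g$cx)^2 + diff(g$cy)^2)
  expect_true(all(gaps[-1] / gaps[-length(gaps)] < 1.5))
  expect_true(all(gaps[-1] / gaps[-length(gaps)] > 1 / 1.5))
  for (i in 2:13) {
    pr <- neighbor_profile(g[i, ], g[-i, ])
    expect_gt(pr$theta, 90)
    expect_lt(pr$ratio, 1.5)
  }
  g3 <- generate_arch(scene_params(teeth_per_arch = 3), seed = 2)
  expect_equal(nrow(g3), 3)
})

test_that("arch boxes stay inside the image over many seeds", {
  p <- scene_params()
  for (seed in seq(1, 100, by = 1)) {
    g <- generate_arch(p, seed = seed)
    expect_true(all(g$cx - g$w / 2 >= 0 & g$cx + g$w / 2 <= p$image_size))
    expect_true(all(g$cy - g$h / 2 >= 0 & g$cy + g$h / 2 <= p$image_size))
  }
})

test_that("emulated score profiles have the constructed shape", {
  p0 <- scene_params(jitter = 0, score_sigma = 0, skew = 0,
                     fn_rate = 0, fp_rate = 0)
  sc <- simulate_scene(p0, seed = 3)
  s <- as.matrix(sc$raw[paste0("s", 0:6)])
  # sigma 0: one-hot at the true class (up to the peak scale)
  expect_equal(max.col(s) - 1L, sc$gts$cls[sc$raw$tooth])
  expect_true(all(rowSums(s > 1e-9) == 1))

  # symmetric profiles: score(t - k) == score(t + k) for interior t
  p1 <- scene_params(jitter = 0, skew = 0, fn_rate = 0, fp_rate = 0,
                     class_priors = c(0, 0, 0, 1, 0, 0, 0))
  sc1 <- simulate_scene(p1, seed = 4)
  s1 <- as.matrix(sc1$raw[paste0("s", 0:6)])
  for (k in 1:3) {
    expect_equal(s1[, 4 - k], s1[, 4 + k], tolerance = 0.15)
  }

  # forced FN: every raw peak of that tooth below 0.5
  p2 <- scene_params(fn_teeth = 3, fp_count = 0)
  sc2 <- simulate_scene(p2, seed = 5)
  peaks <- apply(as.matrix(sc2$raw[paste0("s", 0:6)]), 1, max)
  expect_true(all(peaks[sc2$raw$tooth == 3] < 0.5))
  expect_true(all(peaks[sc2$raw$tooth == 3] >= 0.1))
  expect_true(all(peaks[!is.na(sc2$raw$tooth) & sc2$raw$tooth != 3] >= 0.6))
  expect_equal(sc2$injected_fn, 3L)
})

test_that("planted false positives sit past an arch end with tooth-like scores", {
  p <- scene_params(fp_count = 2)
  sc <- simulate_scene(p, seed = 6)
  expect_equal(length(sc$injected_fp), 2)
  fp <- sc$raw[sc$injected_fp, ]
  expect_true(all(fp$source == "background"))
  peaks <- apply(as.matrix(fp[paste0("s", 0:6)]), 1, max)
  expect_true(all(peaks >= 0.5 & peaks <= 0.8))
  # far from every ground-truth tooth
  for (i in seq_len(nrow(fp))) {
    d <- sqrt((sc$gts$cx - fp$cx[i])^2 + (sc$gts$cy - fp$cy[i])^2)
    expect_gt(min(d), 1.5 * min(dist(cbind(sc$gts$cx, sc$gts$cy))))
  }
})

test_that("scenes are reproducible from their seed", {
  p <- scene_params()
  a <- simulate_scene(p, seed = 77)
  b <- simulate_scene(p, seed = 77)
  expect_identical(a$gts, b$gts)
  expect_identical(a$raw, b$raw)
})

test_that("degradation is seeded, identity at level 0, and grows with level", {
  sc <- simulate_scene(scene_params(), seed = 8)
  expect_identical(degrade_predictions(sc$raw, 0), sc$raw)
  d1 <- degrade_predictions(sc$raw, 1, seed = 9)
  d2 <- degrade_predictions(sc$raw, 1, seed = 9)
  expect_identical(d1, d2)
  # mean absolute score change grows with level (Monte Carlo)
  s0 <- as.matrix(sc$raw[paste0("s", 0:6)])
  changes <- vapply(c(0.5, 1, 2, 4), function(lev) {
    mean(vapply(1:25, function(k) {
      dd <- degrade_predictions(sc$raw, lev, seed = 1000 + k)
      mean(abs(as.matrix(dd[paste0("s", 0:6)]) - s0))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(changes) > 0))
})

test_that("a clean scene yields perfect end-to-end detection", {
  p <- scene_params(jitter = 0, score_sigma = 0, skew = 0,
                    fn_rate = 0, fp_rate = 0)
  sc <- simulate_scene(p, seed = 10)
  dets <- nms_greedy(decode_predictions(sc$raw), 0.1, 0.5)
  expect_equal(nrow(dets), nrow(sc$gts))
  ev <- evaluate_detections(dets, sc$gts)
  expect_equal(ev$map50, 1)
  g <- glance(ev)
  expect_equal(c(g$precision, g$recall), c(1, 1))
})

test_that("skewed profiles make the weighted correction beat the argmax decode", {
  accs <- purrr::map_dfr(1:20, function(seed) {
    p <- scene_params(skew = 1, fn_rate = 0, fp_rate = 0,
                      class_priors = rep(1 / 7, 7))
    sc <- simulate_scene(p, seed = 2000 + seed)
    dets <- nms_greedy(decode_predictions(sc$raw), 0.1, 0.5)
    m <- match_detections(dets, sc$gts, iou_thresh = 0.5)
    truth <- sc$gts$cls[match(dets$tooth, sc$gts$tooth)]
    corrected <- apply_category_correction(dets)
    tibble::tibble(argmax = mean(dets$cls == truth),
                   corrected = mean(corrected$cls == truth))
  })
  expect_gt(mean(accs$corrected), mean(accs$argmax))
  # with every profile skewed the gain is substantial
  expect_gt(mean(accs$corrected) - mean(accs$argmax), 0.2)
})

test_that("datasets round-trip through disk byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p <- scene_params()
  m1 <- generate_dataset(5, p, dir1, seed = 12)
  m2 <- generate_dataset(5, p, dir2, seed = 12)
  expect_identical(readLines(file.path(dir1, "predictions.jsonl")),
                   readLines(file.path(dir2, "predictions.jsonl")))
  back <- read_dataset(dir1)
  expect_equal(nrow(back$gts), 5 * 14)
  expect_equal(back$manifest$n_images, 5)
  # coordinates survive the normalized round-trip
  sc1 <- simulate_scene(p, seed = back$manifest$seeds[1],
                        image_id = "img_0001")
  g1 <- back$gts[back$gts$image_id == "img_0001", ]
  expect_equal(g1$cx, sc1$gts$cx, tolerance = 1e-6)
  expect_equal(g1$cls, sc1$gts$cls)
})
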