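test_that("score boost follows score + w * (1 - score)", {
  expect_equal(boost_score(0), 0.5)
  expect_equal(boost_score(1), 1)
  expect_equal(boost_score(0.2), 0.6)
  expect_error(boost_score(1.2), class = "dentpost_range_error")
  s <- seq(0, 1, by = 0.05)
  expect_true(all(boost_score(s) <= 1))
  expect_true(all(boost_score(s[s < 1]) > s[s < 1]))
})

test_that("parameter validation accepts sweep-range values and rejects nonsense", {
  expect_s3_class(correction_params(), "correction_params")
  expect_no_error(correction_params(fn_ratio = 1))     # lowest sweep point
  expect_no_error(correction_params(fn_ratio = 4))     # above edge_ratio
  expect_error(correction_params(fn_ratio = 0.5))
  expect_error(correction_params(fp_angle_deg = 95))
  expect_error(correction_params(high_conf = 1.2))
})

test_that("simulated missing box sits one d1 step toward the second neighbor", {
  cur <- box_tbl(0, 0, 2, 2)
  nb <- box_tbl(4, 0, 2, 2)
  sim <- simulate_missing_box(cur, nb, d1 = 2)
  expect_equal(sim, box_tbl(2, 0, 2, 2))
  # mirror symmetry
  sim_m <- simulate_missing_box(box_tbl(0, 0, 2, 2), box_tbl(-4, 0, 2, 2), 2)
  expect_equal(sim_m$cx, -2)
  # dimensions are means
  sim_d <- simulate_missing_box(box_tbl(0, 0, 2, 2), box_tbl(4, 0, 4, 4), 2)
  expect_equal(c(sim_d$w, sim_d$h), c(3, 3))
  # midpoint variant
  sim_mid <- simulate_missing_box(cur, nb, d1 = 1.5, placement = "midpoint")
  expect_equal(sim_mid$cx, 2)
  expect_error(simulate_missing_box(cur, cur, 1),
               class = "dentpost_degenerate_geometry_error")
})

test_that("first pass delegates to greedy NMS at the high threshold", {
  set.seed(31)
  d <- random_detections(25, span = 8)
  p <- correction_params()
  expect_equal(plain(high_confidence_pass(d, p)),
               plain(nms_greedy(d, 0.5, 0.5)), ignore_attr = TRUE)
  low <- det_tbl(cx = 1:4, cy = 1, score = 0.4)
  expect_equal(nrow(high_confidence_pass(low, p)), 0)
  one <- det_tbl(cx = 1:4, cy = 1, score = c(0.9, 0.2, 0.2, 0.2))
  expect_equal(nrow(high_confidence_pass(one, p)), 1)
})

test_that("gap rule boosts low-confidence boxes under the simulated tooth", {
  # anchors at x = 0, 2, 6.2 and 8.2 (gap between 2 and 6.2); a
  # low-confidence box sits at 4.1, inside the gap. For the anchor at
  # x = 2: d1 = 2, d2 = 4.2, ratio 2.1 > 2, so a box is simulated at
  # the gap midpoint x = 4.1 (one d1 step, x = 4, under the
  # "distance" placement).
  anchors_x <- c(0, 2, 6.2, 8.2)
  d <- dplyr::bind_rows(
    det_tbl(cx = anchors_x, cy = 0, w = 2, h = 2, score = 0.9),
    det_tbl(cx = 4.1, cy = 0, w = 2, h = 2, score = 0.3)
  )
  p <- correction_params()
  anchors <- high_confidence_pass(d, p)
  expect_equal(sort(anchors$cx), anchors_x)
  adj <- adjust_scores(d, anchors, p)
  expect_equal(attr(adj, "rule_counts")[["R1"]], 1L)
  expect_equal(adj$score[adj$cx == 4.1], 0.65)  # boost(0.3)
  # everything else untouched, bit-identical
  expect_identical(adj$score[adj$cx != 4.1], d$score[d$cx != 4.1])
  expect_identical(as.matrix(adj[adj$cx != 4.1, paste0("s", 0:6)]),
                   as.matrix(d[d$cx != 4.1, paste0("s", 0:6)]))
  # end-to-end at base_conf 0.5: the boosted box now survives
  out <- correct_confidence(d, correction_params(base_conf = 0.5))
  expect_equal(nrow(out), 5)
  base <- nms_greedy(d, 0.5, 0.5)
  expect_equal(nrow(base), 4)
})

test_that("background isolate is suppressed; a mild factor re-ranks, the default removes", {
  # isolated anchor far above two clustered anchors: theta ~ 0,
  # ratio < 2.7, d1 far beyond the typical anchor spacing
  d <- det_tbl(cx = c(0, 1, 0), cy = c(0, 0, 20), w = 1.5, h = 1.5,
               score = c(0.9, 0.85, 0.8))
  p <- correction_params(suppress_factor = 0.5)
  adj <- adjust_scores(d, high_confidence_pass(d, p), p)
  expect_equal(attr(adj, "rule_counts")[["R2"]], 1L)
  expect_equal(adj$score[d$cy == 20], 0.4)
  # with base_conf 0.5 the suppressed isolate is removed
  out <- correct_confidence(d, correction_params(suppress_factor = 0.5,
                                                 base_conf = 0.5))
  expect_equal(nrow(out), 2)
  # default factor 0.1 removes it even at the standard base_conf 0.1
  out2 <- correct_confidence(d, correction_params())
  expect_false(any(out2$cy == 20))
})

test_that("edge rule boosts instead of suppressing when the ratio exceeds edge_ratio", {
  # current box at x = 0 with both neighbors on the same side (theta 0):
  # d1 = 45 (x = 45), d2 = 130 (x = 130), ratio 2.89 > 2.7, and d1 is
  # far beyond the median anchor spacing, so R3 boosts 0.8 -> 0.9
  # rather than suppressing
  d <- det_tbl(cx = c(0, 45, 130, 140), cy = 0, w = 1.5, h = 1.5,
               score = c(0.8, 0.9, 0.85, 0.7))
  p <- correction_params()
  adj <- adjust_scores(d, high_confidence_pass(d, p), p)
  expect_equal(attr(adj, "rule_counts")[["R3"]], 1L)
  expect_equal(attr(adj, "rule_counts")[["R2"]], 0L)
  expect_equal(adj$score[d$cx == 0], 0.9)
})

test_that("fewer than three anchors passes scores through unchanged", {
  d <- det_tbl(cx = c(0, 10, 5), cy = 0, score = c(0.9, 0.8, 0.3))
  p <- correction_params()
  adj <- adjust_scores(d, high_confidence_pass(d, p), p)
  expect_identical(adj$score, d$score)
  expect_equal(sum(attr(adj, "rule_counts")), 0L)
})

test_that("score vectors are rescaled so the maximum equals the new score", {
  d <- dplyr::bind_rows(
    det_tbl(cx = c(0, 2, 6.2, 8.2), cy = 0, w = 2, h = 2, score = 0.9),
    det_tbl(cx = 4.1, cy = 0, w = 2, h = 2, score = 0.3, cls = 4)
  )
  # give the boosted box a non-trivial score profile
  d[5, paste0("s", 0:6)] <- as.list(c(0, 0, 0.1, 0.2, 0.3, 0.15, 0.05))
  p <- correction_params()
  adj <- adjust_scores(d, high_confidence_pass(d, p), p)
  s5 <- as.numeric(adj[5, paste0("s", 0:6)])
  expect_equal(max(s5), adj$score[5])
  expect_equal(s5 / max(s5),
               c(0, 0, 0.1, 0.2, 0.3, 0.15, 0.05) / 0.3)
})

test_that("rule decisions are invariant under uniform scaling and translation", {
  set.seed(41)
  for (rep in 1:10) {
    sc <- simulate_scene(scene_params(fn_teeth = 3, fp_count = 1),
                         seed = 500 + rep)
    dets <- decode_predictions(sc$raw)
    p <- correction_params()
    out0 <- correct_confidence(dets, p)
    moved <- dplyr::mutate(dets, cx = cx * 10 + 1000, cy = cy * 10 + 2000,
                           w = w * 10, h = h * 10)
    out1 <- correct_confidence(moved, p)
    expect_equal(attr(out1, "rule_counts"), attr(out0, "rule_counts"))
    expect_equal(nrow(out1), nrow(out0))
    expect_equal(out1$score, out0$score)
    expect_equal(out1$cx, out0$cx * 10 + 1000)
  }
})

test_that("adjusted scores stay inside [0, 1] and untouched rows are bit-identical", {
  set.seed(42)
  for (rep in 1:10) {
    sc <- simulate_scene(scene_params(fn_rate = 0.5, fp_rate = 1),
                         seed = 600 + rep)
    dets <- decode_predictions(sc$raw)
    p <- correction_params()
    adj <- adjust_scores(dets, high_confidence_pass(dets, p), p)
    expect_true(all(adj$score >= 0 & adj$score <= 1))
    same <- adj$score == dets$score
    expect_identical(adj$cx, dets$cx)
    expect_identical(as.matrix(adj[same, paste0("s", 0:6)]),
                     as.matrix(dets[same, paste0("s", 0:6)]))
  }
})

test_that("the equidistant zero-jitter arch is a no-op region", {
  p <- scene_params(jitter = 0, fn_rate = 0, fp_rate = 0,
                    width_gradient = 0, end_crowding = 1)
  for (seed in c(7, 19, 77)) {
    sc <- simulate_scene(p, seed = seed)
    dets <- decode_predictions(sc$raw)
    corr <- correct_confidence(dets)
    expect_equal(sum(attr(corr, "rule_counts")), 0L)
    expect_identical(plain(corr), plain(nms_greedy(dets, 0.1, 0.5)))
  }
})
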