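test_that("threshold rules use strict inequalities on bin scales", {
  r20 <- matrix(encode_rgb565(20 * 8, 0, 0), 3, 3)   # r5 = 20
  r16 <- matrix(encode_rgb565(16 * 8, 0, 0), 3, 3)   # r5 = 16
  rule <- threshold_rule(r_gt = 16)
  expect_true(all(threshold_segment(r20, rule)))
  expect_false(any(threshold_segment(r16, rule)))    # boundary is excluded
  # malformed rules
  expect_error(threshold_rule(), "at least one bound")
  expect_error(threshold_rule(r_gt = 40), "channel range")
  expect_error(threshold_rule(g_gt = 55, g_lt = 10), "below upper")
  # green bounds above 31 are legal: the G axis has 6 bits
  expect_silent(threshold_rule(g_lt = 55))
})

test_that("threshold_segment matches the per-pixel oracle on random images", {
  set.seed(61)
  rules <- list(
    threshold_rule(r_gt = 16),
    threshold_rule(r_gt = 16, g_lt = 55, b_lt = 12),
    threshold_rule(r_gt = 12, r_lt = 32, g_gt = 10, g_lt = 55, b_gt = 12, b_lt = 16))
  for (rule in rules) {
    codes <- random_codes(12, 15)
    expect_identical(threshold_segment(codes, rule),
                     oracle_threshold_segment(codes, rule))
  }
})

test_that("compute_centroid averages foreground coordinates (0-based)", {
  m <- matrix(FALSE, 30, 40)
  m[11, 21] <- TRUE  # pixel (10, 20) 0-based
  cen <- compute_centroid(m)
  expect_equal(c(cen$row, cen$col), c(10, 20))
  expect_identical(cen$support, 1L)

  m2 <- matrix(FALSE, 12, 12); m2[5:7, 5:7] <- TRUE  # block centered at (5, 5)
  cen2 <- compute_centroid(m2)
  expect_equal(c(cen2$row, cen2$col), c(5, 5))
  expect_identical(cen2$support, 9L)

  m3 <- matrix(FALSE, 20, 20)
  for (p in list(c(0, 0), c(0, 10), c(10, 0), c(10, 10), c(5, 5)))
    m3[p[1] + 1, p[2] + 1] <- TRUE
  cen3 <- compute_centroid(m3)
  expect_equal(c(cen3$row, cen3$col), c(5, 5))
  expect_identical(cen3$support, 5L)

  # empty mask: a distinguished no-detection value, not an error
  cen4 <- compute_centroid(matrix(FALSE, 5, 5))
  expect_false(has_detection(cen4))
  expect_identical(cen4$support, 0L)
})

test_that("compute_centroid is translation-equivariant", {
  set.seed(62)
  base <- matrix(runif(400) < 0.3, 20, 20)
  base[1, ] <- FALSE; base[, 1] <- FALSE  # leave room to shift
  cen <- compute_centroid(base)
  for (shift in list(c(3, 0), c(0, 4), c(5, 7))) {
    shifted <- matrix(FALSE, 30, 30)
    shifted[shift[1] + seq_len(20), shift[2] + seq_len(20)] <- base
    cs <- compute_centroid(shifted)
    expect_equal(c(cs$row, cs$col), c(cen$row + shift[1], cen$col + shift[2]))
  }
})

test_that("largest_component matches the flood-fill oracle under both connectivities", {
  set.seed(63)
  # single blob is unchanged
  blob <- matrix(FALSE, 10, 10); blob[3:6, 4:7] <- TRUE
  expect_identical(largest_component(blob), blob)
  # size 5 vs size 9: the big one survives
  two <- matrix(FALSE, 12, 12)
  two[2:4, 2:4] <- TRUE; two[8:12, 8] <- TRUE
  expect_identical(largest_component(two), {
    keep <- matrix(FALSE, 12, 12); keep[2:4, 2:4] <- TRUE; keep
  })
  # diagonal adjacency joins under 8-connectivity, splits under 4
  diag2 <- matrix(FALSE, 6, 6); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_identical(sum(largest_component(diag2, 8)), 2L)
  expect_identical(sum(largest_component(diag2, 4)), 1L)
  # randomized agreement with the BFS oracle
  for (i in 1:12) {
    m <- matrix(runif(15 * 18) < 0.42, 15, 18)
    for (conn in c(4L, 8L))
      expect_identical(largest_component(m, conn),
                       oracle_largest_component(m, conn))
  }
  # empty mask passes through; ties break on row-major first pixel
  expect_identical(largest_component(matrix(FALSE, 4, 4)), matrix(FALSE, 4, 4))
  tie <- matrix(FALSE, 10, 10)
  tie[6, 1:3] <- TRUE  # first pixel (5, 0): later row but earliest in its row
  tie[1, 5:7] <- TRUE  # first pixel (0, 4): row-major earliest
  expect_identical(largest_component(tie), oracle_largest_component(tie))
  expect_true(largest_component(tie)[1, 5])
})

test_that("track_step runs the normal-to-zoom acquisition state machine", {
  scene <- tiny_scene(seed = 71)
  train <- generate_training_set(2, seed = 72, n_fruit = 2L,
                                 fruit_radius = c(24, 40))
  lut <- histogram_to_lut(fit_histogram(train$images, train$fruit_masks))

  step1 <- track_step(scene$frame, lut)
  expect_true(has_detection(step1$centroid))
  expect_identical(step1$mode, "normal")
  expect_identical(step1$next_state$mode, "zoom")
  # the detected centroid falls inside some ground-truth fruit (QVGA coords)
  gt <- scene_gt_mask(scene, "full", "qvga")
  expect_true(gt[round(step1$centroid$row) + 1, round(step1$centroid$col) + 1])

  # zoom step re-finds the fruit at full resolution
  step2 <- track_step(scene$frame, lut, step1$next_state)
  expect_identical(step2$mode, "zoom")
  expect_true(has_detection(step2$centroid))
  expect_identical(step2$next_state$mode, "zoom")

  # no fruit colors anywhere: no centroid, mode stays normal
  empty_lut <- segmentation_lut(logical(65536))
  step3 <- track_step(scene$frame, empty_lut)
  expect_false(has_detection(step3$centroid))
  expect_identical(step3$next_state$mode, "normal")

  # zoom window that lost the fruit falls back to normal mode
  step4 <- track_step(scene$frame, empty_lut,
                      state = list(mode = "zoom", window_origin = c(0L, 0L)))
  expect_false(has_detection(step4$centroid))
  expect_identical(step4$next_state$mode, "normal")
})

test_that("a LUT encoding a threshold rule reproduces threshold segmentation", {
  lut <- build_lut(function(code) decode_rgb565(code)[, "r5"] > 16L)
  rule <- threshold_rule(r_gt = 16)
  set.seed(64)
  codes <- random_codes(20, 25)
  expect_identical(segment_image(codes, lut), threshold_segment(codes, rule))
})
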