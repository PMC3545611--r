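test_that("area_relative_error follows |pred - gt| / gt", {
  gt <- matrix(FALSE, 20, 20); gt[1:10, 1:10] <- TRUE          # area 100
  expect_equal(area_relative_error(gt, gt), 0)
  pred <- matrix(FALSE, 20, 20); pred[1:9, 1:10] <- TRUE       # 90 inside gt
  expect_equal(area_relative_error(pred, gt), 10)
  # over-segmentation counts too (absolute difference)
  pred2 <- matrix(FALSE, 20, 20); pred2[1:11, 1:10] <- TRUE
  expect_equal(area_relative_error(pred2, gt), 10)
  # random pairs against direct popcount arithmetic
  set.seed(81)
  for (i in 1:10) {
    p <- matrix(runif(400) < 0.4, 20, 20)
    g <- matrix(runif(400) < 0.4, 20, 20)
    if (sum(g) == 0) next
    expect_equal(area_relative_error(p, g), 100 * abs(sum(p) - sum(g)) / sum(g))
    expect_equal(noise_fraction(p, g), 100 * sum(p & !g) / sum(g))
  }
  expect_error(area_relative_error(gt, matrix(FALSE, 20, 20)), "empty ground truth")
  expect_error(noise_fraction(gt, matrix(FALSE, 20, 20)), "empty ground truth")
  expect_error(area_relative_error(gt, matrix(FALSE, 5, 5)), "identical dimensions")
})

test_that("noise_fraction counts only false positives and is monotone in them", {
  gt <- matrix(FALSE, 20, 25); gt[3:12, 3:22] <- TRUE          # area 200
  inside <- gt; inside[3, ] <- FALSE
  expect_equal(noise_fraction(inside, gt), 0)                  # pred subset of gt
  pred <- gt; pred[15, 1:20] <- TRUE                           # 20 pixels outside
  expect_equal(noise_fraction(pred, gt), 10)
  # adding outside pixels never decreases the metric
  prev <- noise_fraction(pred, gt)
  for (j in 1:5) {
    pred[18, j] <- TRUE
    cur <- noise_fraction(pred, gt)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("both metrics are invariant under joint translation", {
  set.seed(82)
  p <- matrix(runif(225) < 0.4, 15, 15)
  g <- matrix(runif(225) < 0.4, 15, 15)
  big_p <- matrix(FALSE, 25, 25); big_g <- matrix(FALSE, 25, 25)
  big_p[1:15, 1:15] <- p; big_g[1:15, 1:15] <- g
  sh_p <- matrix(FALSE, 25, 25); sh_g <- matrix(FALSE, 25, 25)
  sh_p[8 + seq_len(15), 6 + seq_len(15)] <- p
  sh_g[8 + seq_len(15), 6 + seq_len(15)] <- g
  expect_equal(area_relative_error(big_p, big_g), area_relative_error(sh_p, sh_g))
  expect_equal(noise_fraction(big_p, big_g), noise_fraction(sh_p, sh_g))
})

test_that("run_comparison scores every scene under every method with its tags", {
  scenes <- list(tiny_scene(91), tiny_scene(92, illumination = "low"))
  train <- generate_training_set(2, seed = 93, n_fruit = 2L,
                                 fruit_radius = c(24, 40))
  lut <- histogram_to_lut(fit_histogram(train$images, train$fruit_masks))
  rec <- run_comparison(scenes, list(histogram_lut = lut,
                                     empty = segmentation_lut(logical(65536))))
  expect_identical(nrow(rec), 4L)  # scenes x methods
  expect_setequal(unique(rec$method), c("histogram_lut", "empty"))
  expect_identical(rec$illumination[rec$scene_id == scenes[[2]]$scene_id],
                   rep("low", 2L))
  # the empty LUT predicts nothing: area error exactly 100%, zero noise
  expect_true(all(rec$area_rel_error_pct[rec$method == "empty"] == 100))
  expect_true(all(rec$noise_fraction_pct[rec$method == "empty"] == 0))
})

test_that("hand-built two-scene records aggregate to hand arithmetic", {
  rec <- data.frame(
    scene_id = c("a", "a", "b", "b"),
    method = rep(c("m1", "m2"), 2),
    illumination = c("bright", "bright", "bright", "bright"),
    occlusion_bin = rep("none", 4),
    area_rel_error_pct = c(10, 20, 30, 40),
    noise_fraction_pct = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  s <- summarize_comparison(rec, by = "illumination")
  expect_equal(s$area_rel_error_pct[s$method == "m1" & s$illumination == "bright"], 20)
  expect_equal(s$area_rel_error_pct[s$method == "m2" & s$illumination == "bright"], 30)
  expect_equal(s$noise_fraction_pct[s$method == "m1" & s$illumination == "bright"], 2)
  # empty strata are reported missing, never zero
  expect_true(all(is.na(s$area_rel_error_pct[s$illumination == "low"])))
  expect_identical(s$n_scenes[s$illumination == "low"], c(0L, 0L))
})

test_that("the markdown emitter renders the four-table layout with n/a cells", {
  rec <- data.frame(
    scene_id = "a", method = "m1", illumination = "bright",
    occlusion_bin = "none", area_rel_error_pct = 5, noise_fraction_pct = 1,
    stringsAsFactors = FALSE)
  lines <- format_comparison_tables(rec)
  expect_length(grep("^\\*\\*Average", lines), 4L)  # four captioned tables
  expect_true(any(grepl("5.00%", lines)))
  expect_true(any(grepl("n/a", lines)))             # the empty 'low' stratum
})
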