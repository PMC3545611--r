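test_that("fit_color_model recovers a collinear cloud exactly", {
  m <- fit_color_model(rbind(c(100, 0, 0), c(200, 0, 0)), "toy")
  ends <- rbind(m$p0, m$p1)
  expect_equal(ends[order(ends[, 1]), ], rbind(c(100, 0, 0), c(200, 0, 0)),
               ignore_attr = TRUE)
  expect_equal(m$radius, 1)  # radius floor on a zero-spread cloud
})

test_that("fit_color_model radius is the largest perpendicular distance", {
  px <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(10, 5, 0))
  m <- fit_color_model(px, "toy")
  # the principal axis tilts slightly toward the outlier; its distance to
  # the axis must still dominate, and every training pixel must be accepted
  d <- distance_to_model(px, m)
  expect_equal(max(d), m$radius, tolerance = 1e-8)
  expect_true(all(d <= m$radius + 1e-8))
  # axis through the mean: endpoints clipped into the gamut
  big <- fit_color_model(rbind(c(250, 250, 250), c(5, 5, 5)), "diag")
  expect_true(all(big$p0 >= 0 & big$p0 <= 255 & big$p1 >= 0 & big$p1 <= 255))
})

test_that("degenerate pixel clouds are rejected", {
  expect_error(fit_color_model(rbind(c(7, 7, 7), c(7, 7, 7)), "dup"),
               "degenerate")
  expect_error(fit_color_model(matrix(c(1, 2, 3), 1, 3), "single"), "N >= 2")
})

test_that("distance_to_model is the clamped point-to-segment distance", {
  m <- linear_color_model("seg", c(0, 0, 0), c(10, 0, 0), radius = 5)
  expect_equal(distance_to_model(c(3, 0, 0), m), 0)
  expect_equal(distance_to_model(c(0, 0, 5), m), 5)    # perpendicular foot inside
  expect_equal(distance_to_model(c(15, 0, 0), m), 5)   # clamped to endpoint p1
  expect_equal(distance_to_model(c(-3, 4, 0), m), 5)   # clamped to endpoint p0
  # dense-sampling oracle on random segments and points
  set.seed(41)
  for (i in 1:20) {
    p0 <- runif(3, 0, 255); p1 <- runif(3, 0, 255)
    mm <- linear_color_model("r", p0, p1, radius = 1)
    p <- runif(3, -50, 305)
    expect_equal(distance_to_model(p, mm), oracle_segment_distance(p, p0, p1),
                 tolerance = 1e-6)
  }
})

test_that("classify_pixel takes the nearest model, breaks ties low, rejects outliers", {
  ms <- model_set(list(
    linear_color_model("a", c(0, 0, 0), c(10, 0, 0), radius = 12),
    linear_color_model("b", c(0, 20, 0), c(10, 20, 0), radius = 12),
    linear_color_model("c", c(0, 40, 0), c(10, 40, 0), radius = 12)),
    fruit_labels = "a")
  expect_identical(classify_pixel(c(5, 1, 0), ms), "a")
  expect_identical(classify_pixel(c(5, 39, 0), ms), "c")
  # equidistant between models 1 and 2: lowest index wins
  expect_identical(classify_pixel(c(5, 10, 0), ms), "a")
  # farther than every radius: reserved rejection label
  expect_identical(classify_pixel(c(5, 10, 200), ms), "unmodeled")
  expect_identical(classify_pixel(c(5, 10, 200), ms, reject = FALSE), "a")
  expect_error(model_set(list(), "a"), "non-empty")
  expect_error(model_set(list(linear_color_model("a", c(0,0,0), c(1,0,0), 1)),
                         "fruit"), "subset")
})

test_that("LCM-LUT segmentation is identical to direct per-bin classification", {
  ms <- model_set(list(
    linear_color_model("fruit", c(0, 0, 0), c(255, 0, 0), radius = 20),
    linear_color_model("leaf", c(0, 0, 0), c(0, 255, 0), radius = 20)),
    fruit_labels = "fruit")
  lut <- build_lcm_lut(ms)
  # exhaustive popcount against brute-force per-code classification
  reps <- expand_rgb565(0:65535)
  direct <- classify_pixel(reps, ms) == "fruit"
  expect_identical(lut_bins(lut), direct)
  expect_identical(lut$provenance, "lcm")
  # extreme model sets
  all_on <- model_set(list(linear_color_model("f", c(0,0,0), c(255,255,255), 500)),
                      fruit_labels = "f")
  expect_identical(lut_popcount(build_lcm_lut(all_on)), 65536L)
  # a tight fruit model crowded out by a huge competitor sets almost nothing
  ms3 <- model_set(list(linear_color_model("f", c(120, 0, 0), c(130, 0, 0), 0.5),
                        linear_color_model("g", c(0, 0, 0), c(255, 255, 255), 500)),
                   fruit_labels = "f")
  pc <- lut_popcount(build_lcm_lut(ms3))
  expect_gte(pc, 1L)
  expect_lte(pc, 4L)
})

test_that("adding a non-fruit model never turns LUT bins on", {
  set.seed(42)
  ms <- default_model_set()
  lut_full <- build_lcm_lut(ms)
  drop_leaf <- model_set(ms$models[-which(vapply(ms$models, `[[`, character(1),
                                                 "label") == "leaf-bright")],
                         ms$fruit_labels)
  lut_dropped <- build_lcm_lut(drop_leaf)
  # with the competitor removed, the fruit set can only be larger
  expect_true(all(lut_bins(lut_full) <= lut_bins(lut_dropped)))
})

test_that("model sets round-trip through JSON with validation", {
  ms <- default_model_set()
  expect_length(ms$models, 11L)
  expect_setequal(ms$fruit_labels,
                  c("bright-peach", "dark-peach", "yellowish-peach", "brownish-peach"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_set(ms, path)
  back <- read_model_set(path)
  expect_equal(back, ms)
  # invalid files are rejected
  jsonlite::write_json(list(models = list()), path, auto_unbox = TRUE)
  expect_error(read_model_set(path), "fruit_labels")
})

test_that("fit_lcm fits one model per labeled pixel class", {
  set.seed(43)
  sets <- list(
    red = cbind(runif(50, 150, 255), runif(50, 0, 40), runif(50, 0, 40)),
    green = cbind(runif(50, 0, 40), runif(50, 150, 255), runif(50, 0, 40)))
  ms <- fit_lcm(sets, fruit_labels = "red")
  expect_identical(vapply(ms$models, `[[`, character(1), "label"),
                   c("red", "green"))
  expect_identical(classify_pixel(c(220, 20, 20), ms), "red")
  expect_identical(classify_pixel(c(20, 220, 20), ms), "green")
})
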