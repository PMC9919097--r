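px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))

test_that("excess green matches hand-evaluated chromaticity values", {
  expect_equal(excess_green(px(0, 255, 0))[1, 1], 2)
  for (c in c(1, 80, 255))
    expect_equal(excess_green(px(c, c, c))[1, 1], 0)
  expect_equal(excess_green(px(0, 0, 0))[1, 1], 0)   # black maps to 0
  expect_equal(excess_green(px(50, 150, 50))[1, 1], 0.8)
  expect_error(excess_green(matrix(1, 2, 2)), "3")
})

test_that("excess green is invariant under uniform channel scaling", {
  set.seed(1)
  rgb <- array(runif(5 * 5 * 3, 1, 80), c(5, 5, 3))
  for (k in c(0.5, 2, 3.17))
    expect_equal(excess_green(rgb * k), excess_green(rgb), tolerance = 1e-12)
})

test_that("otsu segmentation of a high-contrast scene recovers the truth mask", {
  sc <- generate_canopy_scene(scene_params(width_px = 200L, height_px = 100L),
                              seed = 1)
  mask <- segment_exg(excess_green(sc$rgb))
  agreement <- mean(mask == sc$truth_mask)
  expect_gte(agreement, 0.99)
  expect_identical(attr(mask, "provenance"), "predicted")
})

test_that("hand-rolled otsu agrees with an independent implementation", {
  set.seed(2)
  x <- c(rnorm(400, -0.02, 0.05), rnorm(300, 0.65, 0.08))
  thr <- otsu_threshold(x)
  # EBImage computes otsu on [0, 1]-ranged images; rescale, compare back.
  rng <- range(x)
  img <- matrix((x - rng[1]) / diff(rng), 70, 10)
  thr_eb <- EBImage::otsu(img, range = c(0, 1), levels = 256) * diff(rng) + rng[1]
  expect_equal(thr, thr_eb, tolerance = 2 * diff(rng) / 256)
})

test_that("fixed thresholds beyond the ExG range give single-class masks", {
  exg <- matrix(c(-0.1, 0.2, 0.5, 0.9), 2, 2)
  expect_true(all(segment_exg(exg, "fixed", threshold = 1) == 0L))
  expect_true(all(segment_exg(exg, "fixed", threshold = -1) == 1L))
})

test_that("a constant ExG map with otsu warns and returns an all-soil mask", {
  exg <- matrix(0.3, 4, 4)
  expect_warning(mask <- segment_exg(exg), "single-class")
  expect_true(all(mask == 0L))
})

test_that("reference labeling with zero spread keeps only exact matches", {
  rgb <- array(0L, c(3, 3, 3))
  rgb[1, 1, ] <- c(10, 200, 30)
  rgb[2, 2, ] <- c(10, 200, 30)
  rgb[3, 3, ] <- c(10, 201, 30)   # one channel off
  samples <- cbind(c(1, 2), c(1, 2))
  mask <- reference_labeling(rgb, samples)
  expect_identical(mask[1, 1], 1L)
  expect_identical(mask[2, 2], 1L)
  expect_identical(mask[3, 3], 0L)
  expect_identical(sum(mask), 2L)
})

test_that("reference labeling from plant samples recovers most of the truth mask", {
  # open canopy: the +/-1 sd band misses a fixed share of plant pixels, so
  # whole-image agreement is highest when plants are a minority class
  p <- scene_params(width_px = 200L, height_px = 100L, leaf_length_mm = 36,
                    leaf_width_mm = 14, leaves_per_plant = 6L)
  sc <- generate_canopy_scene(p, seed = 3)
  plant_idx <- which(sc$truth_mask == 1, arr.ind = TRUE)
  set.seed(4)
  samples <- plant_idx[sample(nrow(plant_idx), 10), ]
  mask <- reference_labeling(sc$rgb, samples)
  expect_gte(mean(mask == sc$truth_mask), 0.90)
  expect_identical(attr(mask, "provenance"), "reference")
})

test_that("soil samples label approximately the complement of the plant mask", {
  sc <- generate_canopy_scene(scene_params(width_px = 200L, height_px = 100L),
                              seed = 5)
  soil_idx <- which(sc$truth_mask == 0, arr.ind = TRUE)
  set.seed(6)
  samples <- soil_idx[sample(nrow(soil_idx), 10), ]
  mask <- reference_labeling(sc$rgb, samples)
  complement <- 1L - sc$truth_mask
  # labeled pixels are soil, and the mask tracks the complement, not the plants
  cc <- confusion(mask, complement)
  expect_gte(cc$tp / (cc$tp + cc$fp), 0.95)
  expect_gt(mean(mask == complement), 0.75)
  expect_gt(mean(mask == complement), mean(mask == sc$truth_mask))
})

test_that("out-of-bounds reference samples are rejected", {
  rgb <- array(0L, c(4, 4, 3))
  expect_error(reference_labeling(rgb, cbind(c(1, 5), c(1, 1))), "bounds")
  expect_error(reference_labeling(rgb, cbind(1, 1)), "two sample")
})

test_that("confusion counts match direct enumeration on canonical cases", {
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  same <- confusion(m, m)
  expect_identical(c(same$fp, same$fn), c(0L, 0L))
  flip <- confusion(m, 1L - m)
  expect_identical(c(flip$tp, flip$tn), c(0L, 0L))
  checker <- matrix(rep(c(1L, 0L), 8), 4, 4)
  ones <- matrix(1L, 4, 4)
  cc <- confusion(checker, ones)
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(8L, 0L, 8L, 0L))
  expect_error(confusion(m, matrix(1L, 3, 3)), "dimensions")
})

test_that("metrics honor the perfect and no-true-positive anchors", {
  perfect <- segmentation_metrics(confusion(matrix(c(1L, 0L), 2, 2),
                                            matrix(c(1L, 0L), 2, 2)))
  expect_equal(perfect$f_score, 1)
  expect_equal(perfect$accuracy, 1)
  none <- segmentation_metrics(confusion(matrix(0L, 2, 2), matrix(1L, 2, 2)))
  expect_equal(none$f_score, 0)
  expect_equal(none$precision, 0)
  m <- segmentation_metrics(structure(list(tp = 8L, fp = 2L, fn = 2L, tn = 88L),
                                      class = "confusion_counts"))
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$f_score, 0.8)
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$total_error, 0.04)
})

test_that("metrics stay in [0,1] with the F-score between precision and sensitivity", {
  set.seed(7)
  for (i in 1:25) {
    cc <- confusion(random_mask(16, 16), random_mask(16, 16))
    m <- segmentation_metrics(cc)
    vals <- c(m$precision, m$sensitivity, m$f_score, m$accuracy, m$total_error)
    expect_true(all(vals >= 0 & vals <= 1))
    if (m$precision > 0 && m$sensitivity > 0) {
      expect_lte(m$f_score, max(m$precision, m$sensitivity))
      expect_gte(m$f_score, min(m$precision, m$sensitivity))
    }
  }
})

test_that("label flip swaps precision with the negative-class analogue and keeps accuracy", {
  set.seed(8)
  pred <- random_mask(16, 16); ref <- random_mask(16, 16)
  m <- segmentation_metrics(confusion(pred, ref))
  flipped <- segmentation_metrics(confusion(1L - pred, 1L - ref))
  cc <- confusion(pred, ref)
  npv <- cc$tn / (cc$tn + cc$fn)   # negative predictive value of the original
  expect_equal(flipped$precision, npv)
  expect_equal(flipped$accuracy, m$accuracy)
})

test_that("F-score does not decrease as plant/soil color separation grows", {
  soil <- c(125, 92, 60); green <- c(58, 140, 52)
  f <- vapply(c(0.12, 0.35, 1), function(t) {
    p <- scene_params(width_px = 200L, height_px = 100L,
                      leaf_color = soil + t * (green - soil))
    sc <- generate_canopy_scene(p, seed = 9)
    mask <- segment_exg(excess_green(sc$rgb))
    segmentation_metrics(confusion(mask, sc$truth_mask))$f_score
  }, numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_gt(f[3], f[1])
})
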