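grid_df <- function(nx, ny, t_o = NULL) {
  idx <- expand.grid(x_index = 0:(nx - 1), y_index = 0:(ny - 1))
  idx$t_o <- t_o %||% seq_len(nrow(idx))
  idx$t_a <- 22; idx$rh <- 0.5
  idx
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a complete reading set assembles into a grid in index order", {
  df <- grid_df(2, 2, t_o = c(1, 2, 3, 4))  # (x,y) = (0,0),(1,0),(0,1),(1,1)
  g <- assemble_grid(df)
  expect_identical(dim(g$t_o), c(2L, 2L))
  expect_equal(g$t_o, matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(g$t_a, 22)
})

test_that("a full-bench scan of 1342 readings assembles to 61 x 22", {
  df <- grid_df(61, 22)
  expect_identical(nrow(df), 1342L)
  g <- assemble_grid(df)
  expect_identical(c(g$nx, g$ny), c(61L, 22L))
})

test_that("missing and duplicate cells are reported by index", {
  df <- grid_df(2, 2)
  expect_error(assemble_grid(df[-2, ]), "missing cell.*1 0")
  expect_error(assemble_grid(rbind(df, df[1, ])), "duplicate")
})

test_that("bilinear resize preserves constants and the identity mapping", {
  const <- matrix(4.2, 3, 5)
  expect_equal(max(abs(resize_bilinear(const, c(7, 11)) - 4.2)), 0,
               tolerance = 1e-12)
  m <- matrix(rnorm(12), 3, 4)
  expect_identical(resize_bilinear(m, dim(m)), m)
})

test_that("bilinear resize matches the closed-form midpoint case", {
  m <- matrix(c(0, 0, 1, 1), 2, 2)      # columns [0,0] and [1,1]
  out <- resize_bilinear(m, c(2, 3))
  expect_equal(out[, 2], c(0.5, 0.5))
  expect_equal(out[, 1], c(0, 0))
  expect_equal(out[, 3], c(1, 1))
})

test_that("bilinear output is bounded by the source extrema", {
  set.seed(1)
  for (i in 1:5) {
    m <- matrix(rnorm(30), 5, 6)
    out <- resize_bilinear(m, c(13, 17))
    expect_gte(min(out), min(m))
    expect_lte(max(out), max(m))
  }
  expect_error(resize_bilinear(matrix(1, 1, 3), c(2, 2)), "2 x 2")
  expect_error(resize_bilinear(matrix(1, 3, 3), c(0, 2)), ">= 1")
})

test_that("mask resize stays binary and duplicates cells on integer upscaling", {
  ones <- matrix(1L, 3, 3)
  expect_true(all(resize_mask(ones, c(9, 5)) == 1L))
  checker <- outer(1:4, 1:4, function(i, j) as.integer((i + j) %% 2))
  up <- resize_mask(checker, c(8, 8))
  expect_true(all(up %in% c(0L, 1L)))
  expect_identical(up, checker[rep(1:4, each = 2), rep(1:4, each = 2)])
  block <- matrix(0L, 8, 8); block[3:6, 3:6] <- 1L
  down <- resize_mask(block, c(4, 4))
  expect_true(all(down %in% c(0L, 1L)))
  expect_error(resize_mask(matrix(0.5, 2, 2), c(2, 2)), "binary")
})

test_that("fusion keeps thermal values exactly where the mask marks plant", {
  g <- assemble_grid(grid_df(4, 3))
  mask0 <- matrix(0L, 6, 8)
  expect_true(all(is.na(build_ltm(g, mask0, c(6, 8))$t_l)))
  mask1 <- matrix(1L, 6, 8)
  ltm <- build_ltm(g, mask1, c(6, 8))
  expect_equal(ltm$t_l, resize_bilinear(g$t_o, c(6, 8)))
})

test_that("non-null pixel count equals the resized-mask plant count", {
  sc <- generate_canopy_scene(tiny_scene_params(), seed = 2)
  grid <- simulate_ir_scan(sc, tiny_sensor())
  target <- c(128L, 128L)
  ltm <- build_ltm(grid, sc$truth_mask, target)
  expect_identical(sum(!is.na(ltm$t_l)),
                   sum(resize_mask(sc$truth_mask, target) == 1L))
})

test_that("a uniform-temperature scene fuses to that temperature everywhere", {
  p <- tiny_scene_params(soil_offset = 0, leaf_offsets = c(0, 0, 0),
                         nwsb_a = 0, nwsb_b = 0, temp_noise_sd = 0)
  sc <- generate_canopy_scene(p, seed = 3)
  uniform <- unique(sc$true_temp[sc$truth_mask == 1])
  expect_length(uniform, 1L)
  grid <- simulate_ir_scan(sc, tiny_sensor())
  ltm <- build_ltm(grid, sc$truth_mask, c(128L, 128L))
  vals <- ltm$t_l[!is.na(ltm$t_l)]
  expect_lt(max(abs(vals - uniform)), 1e-6)
})

test_that("fused leaf temperatures track the true leaf mean on a dense canopy", {
  p <- scene_params(width_px = 240L, height_px = 120L, row_spacing_mm = 100,
                    plant_spacing_mm = 50, temp_noise_sd = 0,
                    leaf_length_mm = 55, leaf_width_mm = 20,
                    leaves_per_plant = 8L)
  sc <- generate_canopy_scene(p, seed = 4)
  # fine grid: 10 mm cells, footprint radius 5 mm, limits mixing
  spec <- sensor_spec(grid_nx = 50L, grid_ny = 25L, cell_mm = 10, noise_sd = 0,
                      fov_half_angle = atan(5 / 50) * 180 / pi)
  grid <- simulate_ir_scan(sc, spec)
  ltm <- build_ltm(grid, sc$truth_mask, dim(sc$truth_mask))
  true_mean <- mean(sc$true_temp[sc$truth_mask == 1])
  expect_lt(abs(mean(ltm$t_l, na.rm = TRUE) - true_mean), 0.5)
})

test_that("validation errors match direct evaluation", {
  g <- assemble_grid(grid_df(2, 2, t_o = c(20, 20, 20, 20)))
  ltm <- build_ltm(g, matrix(1L, 1, 2), c(1, 2))
  ltm$t_l <- matrix(c(21, 19), 1, 2)
  rep <- validate_against_reference(ltm, matrix(c(20, 20), 1, 2))
  expect_equal(sort(rep$errors), c(-0.05, 0.05))
  expect_equal(rep$general_mean_error, 0)
  expect_equal(rep$mean_difference_c, 0)

  ltm$t_l <- matrix(c(19.8, NA), 1, 2)
  single <- validate_against_reference(ltm, matrix(c(20, 20), 1, 2))
  expect_equal(single$general_mean_error, -0.01)
  expect_identical(single$n, 1L)
})

test_that("self-validation is exactly zero and zero-reference pixels are excluded", {
  sc <- generate_canopy_scene(tiny_scene_params(), seed = 5)
  grid <- simulate_ir_scan(sc, tiny_sensor())
  ltm <- build_ltm(grid, sc$truth_mask, c(64L, 64L))
  self <- validate_against_reference(ltm, ltm$t_l)
  expect_equal(self$general_mean_error, 0)
  ref <- ltm$t_l
  idx <- which(!is.na(ref))[1:3]
  ref[idx] <- 0
  rep <- validate_against_reference(ltm, ref)
  expect_identical(rep$n_excluded, 3L)
  expect_identical(rep$n, sum(!is.na(ltm$t_l)) - 3L)
})
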