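test_that("baseline-limit CWSI hits the anchors and is linear in between", {
  expect_equal(cwsi_nwsb(0.5, ll = 0.5, ul = 3.1), 0)
  expect_equal(cwsi_nwsb(3.1, ll = 0.5, ul = 3.1), 1)
  expect_equal(cwsi_nwsb(1.8, ll = 0.5, ul = 3.1), 0.5)
  expect_error(cwsi_nwsb(1, ll = 2, ul = 2), "degenerate")
  expect_error(cwsi_nwsb(1, ll = 2, ul = 1), "degenerate")
})

test_that("the literal-denominator variant shares only the zero anchor", {
  expect_equal(cwsi_nwsb(0.5, 0.5, 3.1, denominator = "literal"), 0)
  expect_equal(cwsi_nwsb(1.8, 0.5, 3.1, denominator = "literal"), 1.3 / 1.3)
  expect_gt(cwsi_nwsb(3.0, 0.5, 3.1, denominator = "literal"),
            cwsi_nwsb(3.0, 0.5, 3.1))
})

test_that("empirical CWSI anchors at the wet and dry reference temperatures", {
  refs <- reference_temperatures(19.3, 24.2)
  expect_equal(cwsi_empirical(19.3, refs), 0)
  expect_equal(cwsi_empirical(24.2, refs), 1)
  expect_equal(cwsi_empirical(21.75, refs), 0.5)
  expect_error(reference_temperatures(24.2, 19.3), "exceed")
  expect_error(reference_temperatures(20, 20), "exceed")
})

test_that("both index forms are strictly increasing in leaf temperature", {
  t_l <- seq(18, 26, by = 0.5)
  refs <- reference_temperatures(19.3, 24.2)
  expect_true(all(diff(cwsi_empirical(t_l, refs)) > 0))
  expect_true(all(diff(cwsi_nwsb(t_l - 22.1, ll = 0.5, ul = 3.1)) > 0))
})

test_that("clipping follows the out-of-range correction rule and is idempotent", {
  expect_equal(as.numeric(clip_cwsi(-0.02)), 0)
  expect_equal(as.numeric(clip_cwsi(1.07)), 1)
  expect_equal(as.numeric(clip_cwsi(0.45)), 0.45)
  x <- c(-0.4, 0, 0.3, 1, 1.2, NA)
  once <- clip_cwsi(x)
  expect_identical(as.numeric(clip_cwsi(as.numeric(once))), as.numeric(once))
  expect_identical(attr(once, "n_below"), 1L)
  expect_identical(attr(once, "n_above"), 1L)
  expect_error(clip_cwsi(c(0.2, Inf)), "non-finite")
})

test_that("stress maps preserve the null set and count clip events", {
  sc <- generate_canopy_scene(tiny_scene_params(), seed = 1)
  grid <- simulate_ir_scan(sc, tiny_sensor())
  ltm <- build_ltm(grid, sc$truth_mask, c(64L, 64L))
  env <- generate_environment_series(days = 5, seed = 2)
  obs <- generate_nwsb_observations(env, seed = 3)
  model <- fit_nwsb(obs$dt, obs$vpd)
  smap <- stress_map(ltm, method = "nwsb", model = model)
  expect_identical(is.na(smap$cwsi), is.na(ltm$t_l))
  vals <- smap$cwsi[!is.na(smap$cwsi)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_gte(smap$n_above, 0L)
})

test_that("an all-wet-reference canopy maps to zero stress", {
  g <- assemble_grid(data.frame(x_index = c(0, 1, 0, 1),
                                y_index = c(0, 0, 1, 1),
                                t_o = rep(19.3, 4), t_a = 22.1, rh = 0.47))
  ltm <- build_ltm(g, matrix(1L, 4, 4), c(4L, 4L))
  smap <- stress_map(ltm, method = "empirical",
                     refs = reference_temperatures(19.3, 24.2))
  expect_lt(max(abs(smap$cwsi)), 1e-12)
})

test_that("a single-pixel map equals the scalar empirical index", {
  g <- assemble_grid(data.frame(x_index = c(0, 1, 0, 1),
                                y_index = c(0, 0, 1, 1),
                                t_o = rep(21.75, 4), t_a = 22.1, rh = 0.47))
  mask <- matrix(0L, 2, 2); mask[1, 1] <- 1L
  ltm <- build_ltm(g, mask, c(2L, 2L))
  refs <- reference_temperatures(19.3, 24.2)
  smap <- stress_map(ltm, method = "empirical", refs = refs)
  expect_equal(smap$cwsi[1, 1], as.numeric(clip_cwsi(cwsi_empirical(21.75, refs))))
  expect_identical(sum(!is.na(smap$cwsi)), 1L)
})

test_that("baseline and empirical methods agree when limits coincide", {
  sc <- generate_canopy_scene(tiny_scene_params(), seed = 4)
  grid <- simulate_ir_scan(sc, tiny_sensor())
  ltm <- build_ltm(grid, sc$truth_mask, c(64L, 64L))
  env <- generate_environment_series(days = 5, seed = 5)
  obs <- generate_nwsb_observations(env, seed = 6)
  model <- fit_nwsb(obs$dt, obs$vpd)
  ll <- lower_limit(model, vpd(ltm$t_a, ltm$rh))
  ul <- upper_limit(model, ltm$t_a)
  refs <- reference_temperatures(ltm$t_a + ll, ltm$t_a + ul)
  a <- stress_map(ltm, method = "nwsb", model = model)
  b <- stress_map(ltm, method = "empirical", refs = refs)
  expect_equal(a$cwsi, b$cwsi, tolerance = 1e-12)
})

test_that("treatment means increase with the imposed leaf offsets at zero noise", {
  p <- cycle_scene_params(leaf_offsets = c(0, 0.7, 1.4), temp_noise_sd = 0)
  sc <- generate_canopy_scene(p, seed = 7)
  grid <- simulate_ir_scan(sc, cycle_sensor_spec(noise_sd = 0))
  mask <- segment_exg(excess_green(sc$rgb))
  ltm <- build_ltm(grid, mask, dim(mask))
  env <- generate_environment_series(days = 5, seed = 8)
  obs <- generate_nwsb_observations(env, seed = 9)
  model <- fit_nwsb(obs$dt, obs$vpd)
  smap <- stress_map(ltm, method = "nwsb", model = model)
  summ <- treatment_summary(smap, sc$treatment_layout)
  expect_true(summ$mean_cwsi[1] < summ$mean_cwsi[2])
  expect_true(summ$mean_cwsi[2] < summ$mean_cwsi[3])
})

test_that("treatment summaries partition pixels and average by enumeration", {
  cwsi <- matrix(NA_real_, 4, 6)
  cwsi[1, 1:2] <- 0.1; cwsi[2, 3:4] <- c(0.4, 0.6); cwsi[3, 5] <- 0.9
  layout <- list(T1 = 1:2, T2 = 3:4, T3 = 5:6)
  summ <- treatment_summary(cwsi, layout)
  expect_equal(summ$mean_cwsi, c(0.1, 0.5, 0.9))
  expect_identical(sum(summ$n_pixels), sum(!is.na(cwsi)))
  empty <- treatment_summary(matrix(NA_real_, 2, 3),
                             list(T1 = 1L, T2 = 2L, T3 = 3L))
  expect_identical(empty$n_pixels, rep(0L, 3))
  expect_true(all(is.na(empty$mean_cwsi)))
  expect_error(treatment_summary(cwsi, list(T1 = 1:2, T2 = 2:4, T3 = 5:6)),
               "partition")
})

test_that("uniform stress maps summarize to the same mean in every treatment", {
  cwsi <- matrix(0.45, 3, 9)
  summ <- treatment_summary(cwsi, list(T1 = 1:3, T2 = 4:6, T3 = 7:9))
  expect_equal(summ$mean_cwsi, rep(0.45, 3))
})
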