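#' Scene and sensor defaults for cycle simulation
#'
#' Compact bench used by [simulate_stress_cycle()]: a 600 x 300 mm quarter
#' bench at 2.5 mm/px with rows 100 mm apart, scanned on a 24 x 12 grid of
#' 20 mm cells.  Small enough that a full multi-day chain (scene, scan,
#' segmentation, fusion, stress map) runs in seconds while exercising every
#' stage.
#'
#' @param ... Overrides passed on to [scene_params()].
#' @return A `"scene_params"` object.
#' @export
cycle_scene_params <- function(...) {
  defaults <- list(width_px = 240L, height_px = 120L, pixel_pitch = 2.5,
                   row_spacing_mm = 100, plant_spacing_mm = 50,
                   leaves_per_plant = 8L, leaf_length_mm = 55,
                   leaf_width_mm = 20)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_params, args)
}

#' @rdname cycle_scene_params
#' @export
cycle_sensor_spec <- function(...) {
  # 560 x 280 mm of the 600 x 300 mm scene: the scan covers almost the whole
  # image so the fused map is registered to the mask within one cell
  defaults <- list(grid_nx = 28L, grid_ny = 14L, cell_mm = 20)
  do.call(sensor_spec, utils::modifyList(defaults, list(...)))
}

#' Simulate a full crop cycle of daily stress mapping
#'
#' Runs the complete measurement chain once per day over a simulated crop
#' cycle: the soil-moisture model dries down and triggers irrigation per
#' treatment; each day at noon a scene is generated whose per-treatment
#' leaf-temperature offsets grow with moisture deficit
#' (`offset = stress_gain * (1 - VWC)`), scanned with the infrared sensor,
#' segmented by ExG, fused into a leaf temperature map and scored with the
#' baseline CWSI; per-treatment daily means are collected alongside the
#' noon soil moisture.
#'
#' @param days Cycle length in days.
#' @param params Scene parameters (default [cycle_scene_params()]).
#' @param sensor Sensor specification (default [cycle_sensor_spec()]).
#' @param model Optional [fit_nwsb()] model; when `NULL` one is fitted from
#'   a simulated baseline-bench series under the same environment.
#' @param stress_gain Leaf-temperature offset per unit moisture deficit
#'   (deg C per fraction of field capacity).
#' @param moisture_args,env_args Optional override lists for
#'   [simulate_soil_moisture()] and [generate_environment_series()].
#' @param seed Integer seed; all stage seeds derive from it.
#' @return An object of class `"stress_cycle"`: list with `daily`
#'   (data.frame `day`, `treatment`, `cwsi`, `vwc`), `model`, `moisture`,
#'   `env`.
#' @export
simulate_stress_cycle <- function(days = 30, params = cycle_scene_params(),
                                  sensor = cycle_sensor_spec(), model = NULL,
                                  stress_gain = 3,
                                  moisture_args = list(), env_args = list(),
                                  seed = NULL) {
  check_scalar(days, "days", lower = 1)
  seeds <- derive_seeds(seed, 4L + days)
  env <- do.call(generate_environment_series,
                 utils::modifyList(list(days = days, seed = seeds[[1]]),
                                   env_args))
  moist <- do.call(simulate_soil_moisture,
                   utils::modifyList(list(days = days, seed = seeds[[2]]),
                                     moisture_args))
  if (is.null(model)) {
    obs <- generate_nwsb_observations(env, a = params$nwsb_a, b = params$nwsb_b,
                                      seed = seeds[[3]])
    model <- fit_nwsb(obs$dt, obs$vpd)
  }
  t0 <- env$timestamp[1]
  daily <- vector("list", days)
  for (d in seq_len(days)) {
    noon <- t0 + ((d - 1) * 24 + 12) * 3600
    ei <- which.min(abs(as.numeric(env$timestamp - noon)))
    t_a <- env$t_a[ei]; rh <- env$rh[ei]
    vwc <- vapply(c("T1", "T2", "T3"), function(tr) {
      r <- moist$readings[moist$readings$treatment == tr, ]
      r$vwc[which.min(abs(as.numeric(r$timestamp - noon)))]
    }, numeric(1))
    offsets <- stress_gain * (1 - vwc)
    p <- params
    p$t_a <- t_a; p$rh <- rh; p$leaf_offsets <- unname(offsets)
    # The bench holds the same plants all cycle: one geometry seed for every
    # day, so only the thermal state and the sensor noise change daily.
    scene <- generate_canopy_scene(p, seed = seeds[[4]])
    grid <- simulate_ir_scan(scene, sensor, seed = seeds[[4L + d]])
    mask <- segment_exg(excess_green(scene$rgb))
    ltm <- build_ltm(grid, mask, target_dims = dim(mask))
    smap <- stress_map(ltm, method = "nwsb", model = model)
    summ <- treatment_summary(smap, scene$treatment_layout)
    daily[[d]] <- data.frame(day = d, treatment = summ$treatment,
                             cwsi = summ$mean_cwsi, vwc = unname(vwc))
  }
  structure(list(daily = do.call(rbind, daily), model = model,
                 moisture = moist, env = env),
            class = "stress_cycle")
}

#' @export
print.stress_cycle <- function(x, ...) {
  days <- max(x$daily$day)
  cat(sprintf("<stress_cycle> %d days x 3 treatments\n", days))
  agg <- stats::aggregate(cbind(cwsi, vwc) ~ treatment, x$daily, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
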