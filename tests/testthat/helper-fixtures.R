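# Shared fixtures and independent oracles, all generated in code.

# A 64 x 64 px (160 x 160 mm) mini-bench that keeps scans and chains fast.
tiny_scene_params <- function(...) {
  defaults <- list(width_px = 64L, height_px = 64L, pixel_pitch = 2.5,
                   row_spacing_mm = 60, plant_spacing_mm = 30,
                   leaves_per_plant = 4L, leaf_length_mm = 24,
                   leaf_width_mm = 10)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

tiny_sensor <- function(...) {
  defaults <- list(grid_nx = 3L, grid_ny = 3L, cell_mm = 20, noise_sd = 0,
                   fov_half_angle = atan(15 / 50) * 180 / pi)  # r = 15 mm
  do.call(sensor_spec, utils::modifyList(defaults, list(...)))
}

# Independent scan oracle: enumerate every image pixel, test its center
# against the circular footprint, average.  No bounding boxes, no shortcuts.
brute_force_scan <- function(scene, spec) {
  pitch <- scene$pixel_pitch
  H <- nrow(scene$true_temp); W <- ncol(scene$true_temp)
  nx <- spec$grid_nx; ny <- spec$grid_ny; cell <- spec$cell_mm
  origin <- spec$origin_mm
  if (is.null(origin))
    origin <- c((W * pitch - nx * cell) / 2, (H * pitch - ny * cell) / 2)
  r <- footprint_radius(spec)
  px <- (seq_len(W) - 0.5) * pitch
  py <- (seq_len(H) - 0.5) * pitch
  out <- matrix(NA_real_, ny, nx)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      cx <- origin[1] + (i - 0.5) * cell
      cy <- origin[2] + (j - 0.5) * cell
      acc <- 0; cnt <- 0L
      for (row in seq_len(H)) {
        for (col in seq_len(W)) {
          if ((px[col] - cx)^2 + (py[row] - cy)^2 <= r^2) {
            acc <- acc + scene$true_temp[row, col]
            cnt <- cnt + 1L
          }
        }
      }
      out[j, i] <- acc / cnt
    }
  }
  out
}

# Random 0/1 mask of given dims.
random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# Enumeration oracle for confusion counts.
count_confusion <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && ref[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else if (ref[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# One full measurement chain on the compact bench; returns treatment means.
run_stress_chain <- function(seed, model, leaf_offsets = c(0, 0.7, 1)) {
  p <- cycle_scene_params(leaf_offsets = leaf_offsets)
  sc <- generate_canopy_scene(p, seed = seed)
  grid <- simulate_ir_scan(sc, cycle_sensor_spec(), seed = seed + 1L)
  mask <- segment_exg(excess_green(sc$rgb))
  ltm <- build_ltm(grid, mask, target_dims = dim(mask))
  smap <- stress_map(ltm, method = "nwsb", model = model)
  treatment_summary(smap, sc$treatment_layout)
}
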