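#' Parameters for the synthetic bench-scene generator
#'
#' Bundles and validates every knob of [generate_canopy_scene()].  Defaults
#' emulate an indoor 0.75 m x 1.50 m test bench of row-planted small-leaf
#' plants (rows 0.20 m apart, plants 0.05 m apart within a row) growing on
#' soil, imaged from above at 2.5 mm per pixel, and split into three
#' irrigation treatments laid out as equal column bands.
#'
#' The true temperature field follows a non-water-stressed-baseline model:
#' leaf pixels sit at `T_A + nwsb_a + nwsb_b * VPD(T_A, RH)` plus the
#' per-treatment additive offset, soil pixels at `T_A + soil_offset` (soil
#' runs warmer than transpiring leaves).  Leaf color is a Gaussian-perturbed
#' green, soil a Gaussian-perturbed brown; most of the color noise is a
#' brightness term shared by the three channels, as illumination dominates
#' natural color variation, with a smaller independent per-channel term.
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param pixel_pitch Physical size of one image pixel (mm).
#' @param row_spacing_mm,plant_spacing_mm Row and in-row plant spacing (mm).
#' @param plant_density Probability in `[0, 1]` that a lattice position holds
#'   a plant; 0 gives a bare-soil scene.
#' @param leaves_per_plant Number of elliptical leaves drawn per plant.
#' @param leaf_length_mm,leaf_width_mm Nominal leaf axis lengths (mm).
#' @param leaf_size_sd Relative standard deviation of leaf axis lengths.
#' @param leaf_color,soil_color Base 8-bit RGB triples.
#' @param brightness_sd Standard deviation of the shared per-pixel brightness
#'   perturbation (8-bit counts).
#' @param channel_sd Standard deviation of the independent per-channel
#'   perturbation (8-bit counts).
#' @param t_a,rh Ambient temperature (deg C) and relative humidity (fraction
#'   in `[0, 1]`) at scene time.
#' @param nwsb_a,nwsb_b Intercept (deg C) and slope (deg C / kPa) of the
#'   baseline model driving leaf temperature.
#' @param soil_offset Soil-minus-ambient temperature offset (deg C).
#' @param leaf_offsets Length-3 additive leaf-temperature offsets (deg C),
#'   one per treatment, expressing increasing imposed stress.
#' @param temp_noise_sd Per-pixel Gaussian noise on the true temperature
#'   field (deg C); 0 gives an exactly piecewise-constant field.
#' @param emissivity Leaf emissivity carried as instrument metadata (the
#'   simulated readings are not radiometrically modelled).
#'
#' @return A validated list of class `"scene_params"`.
#' @seealso [generate_canopy_scene()]
#' @export
scene_params <- function(width_px = 600L, height_px = 300L, pixel_pitch = 2.5,
                         row_spacing_mm = 200, plant_spacing_mm = 50,
                         plant_density = 1,
                         leaves_per_plant = 12L,
                         leaf_length_mm = 110, leaf_width_mm = 40,
                         leaf_size_sd = 0.15,
                         leaf_color = c(58, 140, 52),
                         soil_color = c(125, 92, 60),
                         brightness_sd = 10, channel_sd = 3,
                         t_a = 22.1, rh = 0.47,
                         nwsb_a = 2.54, nwsb_b = -1.71,
                         soil_offset = 3,
                         leaf_offsets = c(0, 0.7, 1),
                         temp_noise_sd = 0.1,
                         emissivity = 0.98) {
  check_scalar(width_px, "width_px", lower = 1)
  check_scalar(height_px, "height_px", lower = 1)
  check_scalar(pixel_pitch, "pixel_pitch", lower = 0, strict_lower = TRUE)
  check_scalar(row_spacing_mm, "row_spacing_mm", lower = 0, strict_lower = TRUE)
  check_scalar(plant_spacing_mm, "plant_spacing_mm", lower = 0, strict_lower = TRUE)
  check_scalar(plant_density, "plant_density", lower = 0, upper = 1)
  check_scalar(leaves_per_plant, "leaves_per_plant", lower = 1)
  check_scalar(leaf_length_mm, "leaf_length_mm", lower = 0, strict_lower = TRUE)
  check_scalar(leaf_width_mm, "leaf_width_mm", lower = 0, strict_lower = TRUE)
  check_scalar(leaf_size_sd, "leaf_size_sd", lower = 0)
  check_scalar(brightness_sd, "brightness_sd", lower = 0)
  check_scalar(channel_sd, "channel_sd", lower = 0)
  check_scalar(rh, "rh", lower = 0, upper = 1)
  check_scalar(soil_offset, "soil_offset")
  check_scalar(temp_noise_sd, "temp_noise_sd", lower = 0)
  check_scalar(emissivity, "emissivity", lower = 0, upper = 1,
               strict_lower = TRUE)
  stopifnot(length(leaf_color) == 3L, length(soil_color) == 3L,
            length(leaf_offsets) == 3L)
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_pitch = pixel_pitch,
    row_spacing_mm = row_spacing_mm, plant_spacing_mm = plant_spacing_mm,
    plant_density = plant_density,
    leaves_per_plant = as.integer(leaves_per_plant),
    leaf_length_mm = leaf_length_mm, leaf_width_mm = leaf_width_mm,
    leaf_size_sd = leaf_size_sd,
    leaf_color = leaf_color, soil_color = soil_color,
    brightness_sd = brightness_sd, channel_sd = channel_sd,
    t_a = t_a, rh = rh, nwsb_a = nwsb_a, nwsb_b = nwsb_b,
    soil_offset = soil_offset, leaf_offsets = leaf_offsets,
    temp_noise_sd = temp_noise_sd, emissivity = emissivity
  ), class = "scene_params")
}

# Split W columns into three contiguous, disjoint treatment bands.
treatment_layout_for <- function(width_px) {
  bands <- cut(seq_len(width_px), 3L, labels = FALSE)
  stats::setNames(split(seq_len(width_px), bands), c("T1", "T2", "T3"))
}

# Rasterize one ellipse onto a mask: pixel centers at ((col-0.5)*pitch,
# (row-0.5)*pitch) mm; membership by center-inside test.
rasterize_ellipse <- function(mask, cx, cy, a, b, theta, pitch) {
  H <- nrow(mask); W <- ncol(mask)
  rmax <- max(a, b)
  c0 <- max(1L, floor((cx - rmax) / pitch + 0.5))
  c1 <- min(W, ceiling((cx + rmax) / pitch + 0.5))
  r0 <- max(1L, floor((cy - rmax) / pitch + 0.5))
  r1 <- min(H, ceiling((cy + rmax) / pitch + 0.5))
  if (c0 > c1 || r0 > r1) return(mask)
  cols <- c0:c1; rows <- r0:r1
  px <- (cols - 0.5) * pitch - cx
  py <- (rows - 0.5) * pitch - cy
  ct <- cos(theta); st <- sin(theta)
  u <- outer(py * st, px * ct, "+")   # rotated major-axis coordinate
  v <- outer(py * ct, -px * st, "+")  # rotated minor-axis coordinate
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- mask[rows, cols, drop = FALSE]
  sub[inside] <- 1L
  mask[rows, cols] <- sub
  mask
}

#' Generate a synthetic bench scene with known ground truth
#'
#' Draws row-planted plants as clusters of overlapping elliptical leaves on a
#' soil background and derives the co-registered true surface-temperature
#' field and plant mask, so every downstream stage (segmentation, scanning,
#' fusion, stress mapping) can be tested against exact ground truth.
#'
#' @param params A [scene_params()] object.
#' @param seed Optional integer seed; fixed seed and parameters give a
#'   byte-identical scene.
#'
#' @return An object of class `"canopy_scene"`: a list with `rgb`
#'   (`H x W x 3` integer array, 0-255), `true_temp` (`H x W` deg C matrix),
#'   `truth_mask` (`H x W` 0/1 matrix, 1 = plant), `pixel_pitch` (mm),
#'   `treatment_layout` (named list of column indices per treatment),
#'   `leaf_offsets`, `emissivity`, `t_a`, `rh`, and the `params` echo.
#' @examples
#' sc <- generate_canopy_scene(scene_params(width_px = 120, height_px = 60,
#'                                          row_spacing_mm = 60,
#'                                          plant_spacing_mm = 30), seed = 1)
#' mean(sc$truth_mask)   # plant cover fraction
#' @export
generate_canopy_scene <- function(params = scene_params(), seed = NULL) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  if (!is.null(seed)) set.seed(seed)
  H <- params$height_px; W <- params$width_px
  pitch <- params$pixel_pitch
  w_mm <- W * pitch; h_mm <- H * pitch

  # Noise fields are drawn first so the random stream consumed by the canopy
  # geometry is independent of the color model.
  bright <- matrix(stats::rnorm(H * W, 0, params$brightness_sd), H, W)
  chan <- array(stats::rnorm(H * W * 3L, 0, params$channel_sd), c(H, W, 3L))

  mask <- matrix(0L, H, W)
  rows_y <- seq(params$row_spacing_mm / 2, h_mm, by = params$row_spacing_mm)
  plants_x <- seq(params$plant_spacing_mm / 2, w_mm, by = params$plant_spacing_mm)
  jitter_sd <- params$leaf_length_mm / 4
  for (y0 in rows_y) {
    for (x0 in plants_x) {
      if (stats::runif(1) > params$plant_density) next
      for (k in seq_len(params$leaves_per_plant)) {
        cx <- x0 + stats::rnorm(1, 0, jitter_sd)
        cy <- y0 + stats::rnorm(1, 0, jitter_sd)
        theta <- stats::runif(1, 0, pi)
        a <- params$leaf_length_mm / 2 * max(0.3, 1 + stats::rnorm(1, 0, params$leaf_size_sd))
        b <- params$leaf_width_mm / 2 * max(0.3, 1 + stats::rnorm(1, 0, params$leaf_size_sd))
        mask <- rasterize_ellipse(mask, cx, cy, a, b, theta, pitch)
      }
    }
  }

  rgb <- array(0L, c(H, W, 3L))
  plant <- mask == 1L
  for (ch in 1:3) {
    base <- matrix(params$soil_color[ch], H, W)
    base[plant] <- params$leaf_color[ch]
    rgb[, , ch] <- as.integer(round(clamp(base + bright + chan[, , ch], 0, 255)))
  }

  layout <- treatment_layout_for(W)
  vpd_now <- vpd(params$t_a, params$rh)
  leaf_base <- params$t_a + params$nwsb_a + params$nwsb_b * vpd_now
  treat_of_col <- rep(NA_integer_, W)
  for (k in 1:3) treat_of_col[layout[[k]]] <- k
  offset_mat <- matrix(params$leaf_offsets[treat_of_col], H, W, byrow = TRUE)
  true_temp <- matrix(params$t_a + params$soil_offset, H, W)
  true_temp[plant] <- leaf_base + offset_mat[plant]
  if (params$temp_noise_sd > 0)
    true_temp <- true_temp + matrix(stats::rnorm(H * W, 0, params$temp_noise_sd), H, W)

  structure(list(
    rgb = rgb, true_temp = true_temp, truth_mask = mask,
    pixel_pitch = pitch, treatment_layout = layout,
    leaf_offsets = params$leaf_offsets, emissivity = params$emissivity,
    t_a = params$t_a, rh = params$rh, params = params
  ), class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene> %d x %d px (%.1f mm/px), plant cover %.1f%%\n",
              nrow(x$truth_mask), ncol(x$truth_mask), x$pixel_pitch,
              100 * mean(x$truth_mask)))
  cat(sprintf("  T_A %.1f degC, RH %.0f%%, leaf offsets %s degC, emissivity %.2f\n",
              x$t_a, 100 * x$rh, paste(x$leaf_offsets, collapse = "/"),
              x$emissivity))
  invisible(x)
}
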