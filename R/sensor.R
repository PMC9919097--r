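#' Infrared scanning-sensor specification
#'
#' Describes the gantry-mounted infrared thermometer used by
#' [simulate_ir_scan()]: a sensor with a conical field of view held at a
#' fixed height above the canopy, read on a rectangular grid of scan cells.
#' The reading of one cell is the mean surface temperature over the circular
#' ground footprint of radius `height_mm * tan(fov_half_angle)`.
#'
#' The default half angle of 12 degrees represents a collimated sensor whose
#' footprint (radius ~10.6 mm at 50 mm height) roughly matches the 20 mm
#' scan cell; an uncollimated 90-degree conical field of view corresponds to
#' `fov_half_angle = 45`.  `noise_sd = 0.25` deg C places about 95% of
#' readings within a +/-0.5 deg C instrument precision.
#'
#' @param height_mm Sensor height above the canopy (mm).
#' @param fov_half_angle Half angle of the conical field of view (degrees).
#' @param noise_sd Gaussian read-noise standard deviation (deg C).
#' @param grid_nx,grid_ny Scan grid dimensions (cells along x and y).
#' @param cell_mm Scan cell size (mm).
#' @param origin_mm Optional `c(x, y)` offset (mm) of the grid's corner from
#'   the scene's corner; `NULL` centers the grid on the scene.
#' @return An object of class `"sensor_spec"`.
#' @export
sensor_spec <- function(height_mm = 50, fov_half_angle = 12, noise_sd = 0.25,
                        grid_nx = 61L, grid_ny = 22L, cell_mm = 20,
                        origin_mm = NULL) {
  check_scalar(height_mm, "height_mm", lower = 0, strict_lower = TRUE)
  check_scalar(fov_half_angle, "fov_half_angle", lower = 0, upper = 90,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(grid_nx, "grid_nx", lower = 1)
  check_scalar(grid_ny, "grid_ny", lower = 1)
  check_scalar(cell_mm, "cell_mm", lower = 0, strict_lower = TRUE)
  if (!is.null(origin_mm)) stopifnot(length(origin_mm) == 2L)
  structure(list(height_mm = height_mm, fov_half_angle = fov_half_angle,
                 noise_sd = noise_sd, grid_nx = as.integer(grid_nx),
                 grid_ny = as.integer(grid_ny), cell_mm = cell_mm,
                 origin_mm = origin_mm),
            class = "sensor_spec")
}

#' Ground footprint radius of the sensor field of view
#'
#' @param spec A [sensor_spec()].
#' @return Radius in mm of the circular reading area.
#' @export
footprint_radius <- function(spec) {
  spec$height_mm * tan(spec$fov_half_angle * pi / 180)
}

#' Simulate an infrared scan of a synthetic scene
#'
#' Reads the scene's true temperature field on the sensor's scan grid.  Each
#' cell's object temperature `T_O` is the mean of the true field over the
#' image pixels whose centers fall inside the circular footprint centered on
#' the cell, plus Gaussian read noise; a cell's footprint may cover plant
#' pixels, soil pixels, or a mixture of both.  Ambient temperature and
#' relative humidity at scan time are attached as scan-level metadata.
#'
#' If the footprint radius is smaller than one image pixel the reading
#' degrades to nearest-pixel sampling, with a warning.
#'
#' @param scene A [generate_canopy_scene()] result.
#' @param spec A [sensor_spec()]; its grid footprint must lie inside the
#'   scene bounds.
#' @param t_a,rh Ambient conditions at scan time (default: the scene's).
#' @param seed Optional integer seed for the read noise.
#' @param timestamp Optional scan timestamp (`POSIXct`), metadata only.
#' @return An object of class `"thermal_grid"` (see [assemble_grid()]).
#' @export
simulate_ir_scan <- function(scene, spec = sensor_spec(), t_a = scene$t_a,
                             rh = scene$rh, seed = NULL, timestamp = NULL) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(spec, "sensor_spec"))
  if (!is.null(seed)) set.seed(seed)
  pitch <- scene$pixel_pitch
  H <- nrow(scene$true_temp); W <- ncol(scene$true_temp)
  w_mm <- W * pitch; h_mm <- H * pitch
  nx <- spec$grid_nx; ny <- spec$grid_ny; cell <- spec$cell_mm
  origin <- spec$origin_mm %||% c((w_mm - nx * cell) / 2, (h_mm - ny * cell) / 2)
  if (any(origin < 0))
    stop("scan grid is larger than the scene", call. = FALSE)
  r <- footprint_radius(spec)
  cx <- origin[1] + (seq_len(nx) - 0.5) * cell
  cy <- origin[2] + (seq_len(ny) - 0.5) * cell
  if (min(cx) - r < 0 || max(cx) + r > w_mm || min(cy) - r < 0 || max(cy) + r > h_mm)
    stop("scan footprint extends outside the scene; shrink the grid, ",
         "the field of view, or enlarge the scene", call. = FALSE)
  nearest <- r < pitch
  if (nearest)
    warning("footprint radius (", signif(r, 3), " mm) is smaller than one ",
            "image pixel; degrading to nearest-pixel sampling", call. = FALSE)
  px <- (seq_len(W) - 0.5) * pitch
  py <- (seq_len(H) - 0.5) * pitch
  t_o <- matrix(NA_real_, ny, nx)
  for (j in seq_len(ny)) {
    rows <- which(abs(py - cy[j]) <= r)
    dy2 <- (py[rows] - cy[j])^2
    for (i in seq_len(nx)) {
      if (nearest) {
        t_o[j, i] <- scene$true_temp[which.min(abs(py - cy[j])),
                                     which.min(abs(px - cx[i]))]
      } else {
        cols <- which(abs(px - cx[i]) <= r)
        inside <- outer(dy2, (px[cols] - cx[i])^2, "+") <= r^2
        t_o[j, i] <- mean(scene$true_temp[rows, cols, drop = FALSE][inside])
      }
    }
  }
  if (spec$noise_sd > 0)
    t_o <- t_o + matrix(stats::rnorm(nx * ny, 0, spec$noise_sd), ny, nx)
  new_thermal_grid(t_o, cell_mm = cell, origin_mm = origin, t_a = t_a, rh = rh,
                   timestamp = timestamp, noise_sd = spec$noise_sd,
                   footprint_radius_mm = r)
}

new_thermal_grid <- function(t_o, cell_mm, origin_mm = c(0, 0), t_a = NA_real_,
                             rh = NA_real_, timestamp = NULL,
                             noise_sd = NA_real_,
                             footprint_radius_mm = NA_real_) {
  structure(list(t_o = t_o, nx = ncol(t_o), ny = nrow(t_o),
                 cell_mm = cell_mm, origin_mm = origin_mm,
                 t_a = t_a, rh = rh, timestamp = timestamp,
                 noise_sd = noise_sd,
                 footprint_radius_mm = footprint_radius_mm),
            class = "thermal_grid")
}

#' @export
print.thermal_grid <- function(x, ...) {
  cat(sprintf("<thermal_grid> %d x %d cells of %.0f mm, T_O %.2f..%.2f degC\n",
              x$nx, x$ny, x$cell_mm, min(x$t_o), max(x$t_o)))
  cat(sprintf("  scan T_A %.1f degC, RH %.0f%%\n", x$t_a, 100 * x$rh))
  invisible(x)
}
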