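# File-format interfaces: CSV rasters and series, PNG images, JSON reports.

#' Write / read a numeric raster as CSV
#'
#' Plain-text raster exchange format: comment header lines carry the
#' dimensions and (optionally) the pixel pitch, followed by one CSV row per
#' raster row.  `NA` entries encode the no-data sentinel.
#'
#' @param raster Numeric matrix.
#' @param path Output file.
#' @param pixel_pitch Optional pixel size in mm, stored in the header.
#' @return `path`, invisibly (writer); the matrix with a `pixel_pitch`
#'   attribute (reader).
#' @export
write_raster_csv <- function(raster, path, pixel_pitch = NA_real_) {
  check_raster(raster, "raster")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims: %d %d", nrow(raster), ncol(raster)), con)
  if (!is.na(pixel_pitch))
    writeLines(sprintf("# pixel_pitch_mm: %g", pixel_pitch), con)
  utils::write.table(raster, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  header <- readLines(path, n = 2L)
  pitch <- NA_real_
  m <- grep("^# pixel_pitch_mm:", header, value = TRUE)
  if (length(m)) pitch <- as.numeric(sub("^# pixel_pitch_mm:\\s*", "", m[1]))
  out <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#",
                                     header = FALSE))
  dimnames(out) <- NULL
  attr(out, "pixel_pitch") <- pitch
  out
}

#' Write / read a thermal grid as CSV
#'
#' One row per scan cell with 0-based indices, physical cell-center
#' coordinates, the object temperature, and the ambient context:
#' columns `x_index`, `y_index`, `x_mm`, `y_mm`, `t_o`, `t_a`, `rh`.
#'
#' @param grid A `"thermal_grid"`.
#' @param path CSV file path.
#' @return `path`, invisibly (writer); a `"thermal_grid"` (reader).
#' @export
write_thermal_grid <- function(grid, path) {
  stopifnot(inherits(grid, "thermal_grid"))
  idx <- expand.grid(x_index = 0:(grid$nx - 1L), y_index = 0:(grid$ny - 1L))
  df <- data.frame(
    x_index = idx$x_index, y_index = idx$y_index,
    x_mm = grid$origin_mm[1] + (idx$x_index + 0.5) * grid$cell_mm,
    y_mm = grid$origin_mm[2] + (idx$y_index + 0.5) * grid$cell_mm,
    t_o = grid$t_o[cbind(idx$y_index + 1L, idx$x_index + 1L)],
    t_a = grid$t_a, rh = grid$rh)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thermal_grid
#' @export
read_thermal_grid <- function(path) {
  df <- utils::read.csv(path)
  cell <- if (nrow(df) > 1) {
    xs <- sort(unique(df$x_mm))
    if (length(xs) > 1) xs[2] - xs[1] else 20
  } else 20
  origin <- c(min(df$x_mm) - 0.5 * cell, min(df$y_mm) - 0.5 * cell)
  assemble_grid(df, cell_mm = cell, origin_mm = origin)
}

#' Write a time-stamped series as CSV
#'
#' Timestamps are written in ISO-8601 (`YYYY-MM-DDTHH:MM:SS`, UTC).
#'
#' @param df Data.frame with a `timestamp` column.
#' @param path CSV file path.
#' @return `path`, invisibly (writer); the data.frame with POSIXct
#'   timestamps (reader).
#' @export
write_series_csv <- function(df, path) {
  stopifnot(is.data.frame(df), "timestamp" %in% names(df))
  out <- df
  out$timestamp <- iso8601(df$timestamp)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  df
}

#' Write a scene's artifacts to a directory
#'
#' Exports the RGB image as PNG and the true temperature field and truth
#' mask as CSV rasters with the pixel pitch in their headers.
#'
#' @param scene A `"canopy_scene"`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "canopy_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rgb = file.path(dir, "rgb.png"),
             true_temp = file.path(dir, "true_temp.csv"),
             truth_mask = file.path(dir, "truth_mask.csv"))
  png::writePNG(scene$rgb / 255, paths[["rgb"]])
  write_raster_csv(scene$true_temp, paths[["true_temp"]], scene$pixel_pitch)
  write_raster_csv(scene$truth_mask, paths[["truth_mask"]], scene$pixel_pitch)
  invisible(paths)
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' @param mask 0/1 matrix.
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  mask <- check_binary_mask(mask, "mask")
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

# Fixed 0-1 color scale for stress maps: blue (0) -> yellow -> red (1);
# no-plant pixels render mid-gray.
stress_colors <- function(values) {
  ramp <- grDevices::colorRamp(c("#2166ac", "#ffffbf", "#b2182b"))
  out <- matrix(0.5, length(values), 3)
  ok <- !is.na(values)
  if (any(ok)) out[ok, ] <- ramp(clamp(values[ok], 0, 1)) / 255
  out
}

#' Write a stress map as CSV and PNG preview
#'
#' The CSV raster uses `NA` for off-plant pixels; the PNG preview renders
#' CWSI on a fixed 0-1 color scale (blue to red) with off-plant pixels in
#' gray.
#'
#' @param smap A `"stress_map"`.
#' @param csv_path CSV raster path.
#' @param png_path Optional PNG preview path.
#' @return Written paths, invisibly.
#' @export
write_stress_map <- function(smap, csv_path, png_path = NULL) {
  stopifnot(inherits(smap, "stress_map"))
  write_raster_csv(smap$cwsi, csv_path)
  if (!is.null(png_path)) {
    H <- nrow(smap$cwsi); W <- ncol(smap$cwsi)
    img <- array(stress_colors(as.vector(smap$cwsi)), c(H, W, 3))
    png::writePNG(img, png_path)
  }
  invisible(c(csv = csv_path, png = png_path))
}

#' Write a leaf temperature map as CSV plus PNG preview
#'
#' @param ltm A `"leaf_temperature_map"`.
#' @param csv_path CSV raster path (`NA` marks off-plant pixels).
#' @param png_path Optional grayscale preview (temperature range rescaled
#'   to 0-1, off-plant black).
#' @return Written paths, invisibly.
#' @export
write_ltm <- function(ltm, csv_path, png_path = NULL) {
  stopifnot(inherits(ltm, "leaf_temperature_map"))
  write_raster_csv(ltm$t_l, csv_path)
  if (!is.null(png_path)) {
    v <- ltm$t_l
    rng <- range(v, na.rm = TRUE)
    g <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0 + 0.5
    g[is.na(g)] <- 0
    png::writePNG(g, png_path)
  }
  invisible(c(csv = csv_path, png = png_path))
}

# JSON writer used for models, metrics and reports (plain lists).
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) document of pipeline
#' parameters and merges it over [default_run_config()].
#'
#' @param path Configuration file path.
#' @return A run-configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
                 yml = , yaml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 stop("unsupported config format: .", ext, call. = FALSE))
  utils::modifyList(default_run_config(), user)
}
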