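#' Assemble a thermal grid from per-cell scan readings
#'
#' Builds the soil/plant thermal map from a sequence of point readings taken
#' on the scan grid.  The readings must form a complete rectangle of 0-based
#' `(x_index, y_index)` cells with no duplicates; scan-level ambient
#' temperature and relative humidity are taken as the mean of the per-cell
#' context columns.
#'
#' @param readings A data.frame with columns `x_index`, `y_index` (0-based
#'   integers), `t_o` (deg C), and optionally `t_a`, `rh`.
#' @param cell_mm Scan cell size (mm).
#' @param origin_mm Grid corner offset `c(x, y)` in mm.
#' @param timestamp Optional scan timestamp.
#' @return An object of class `"thermal_grid"`: list with `t_o`
#'   (`ny x nx` matrix), `nx`, `ny`, `cell_mm`, `origin_mm`, `t_a`, `rh`.
#' @export
assemble_grid <- function(readings, cell_mm = 20, origin_mm = c(0, 0),
                          timestamp = NULL) {
  stopifnot(is.data.frame(readings),
            all(c("x_index", "y_index", "t_o") %in% names(readings)))
  xi <- as.integer(readings$x_index)
  yi <- as.integer(readings$y_index)
  if (any(xi < 0) || any(yi < 0))
    stop("cell indices must be 0-based non-negative integers", call. = FALSE)
  key <- paste(xi, yi)
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicate cell indices: ", paste(unique(dup), collapse = "; "),
         call. = FALSE)
  nx <- max(xi) + 1L; ny <- max(yi) + 1L
  want <- expand.grid(x = 0:(nx - 1L), y = 0:(ny - 1L))
  missing <- setdiff(paste(want$x, want$y), key)
  if (length(missing))
    stop("incomplete scan: missing cell indices (x y): ",
         paste(utils::head(missing, 10L), collapse = "; "),
         if (length(missing) > 10L) " ..." else "", call. = FALSE)
  t_o <- matrix(NA_real_, ny, nx)
  t_o[cbind(yi + 1L, xi + 1L)] <- readings$t_o
  t_a <- if ("t_a" %in% names(readings)) mean(readings$t_a) else NA_real_
  rh <- if ("rh" %in% names(readings)) mean(readings$rh) else NA_real_
  new_thermal_grid(t_o, cell_mm = cell_mm, origin_mm = origin_mm,
                   t_a = t_a, rh = rh, timestamp = timestamp)
}

# Corner-aligned source coordinates (0-based) for resampling `n_src` samples
# onto `n_dst`.
resample_coords <- function(n_src, n_dst) {
  if (n_dst == 1L) return(0)
  seq(0, n_src - 1, length.out = n_dst)
}

#' Bilinear raster resizing
#'
#' Resamples a numeric raster to `target_dims` with bilinear interpolation
#' under corner-aligned coordinate mapping: output sample `i` (0-based) of
#' `n` maps to source coordinate `i * (n_src - 1) / (n - 1)`, so the corners
#' of the two rasters coincide.  Output values are convex combinations of
#' source values and therefore never exceed the source extrema.
#'
#' @param raster A numeric matrix, at least 2 x 2.
#' @param target_dims Integer `c(H, W)`, both >= 1.
#' @return A `target_dims[1] x target_dims[2]` numeric matrix.
#' @export
resize_bilinear <- function(raster, target_dims) {
  check_raster(raster, "raster")
  if (nrow(raster) < 2L || ncol(raster) < 2L)
    stop("source raster must be at least 2 x 2", call. = FALSE)
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 2L || any(target_dims < 1L))
    stop("`target_dims` must be two integers >= 1", call. = FALSE)
  if (identical(target_dims, dim(raster))) return(raster)
  H <- target_dims[1]; W <- target_dims[2]
  ys <- resample_coords(nrow(raster), H)
  xs <- resample_coords(ncol(raster), W)
  y0 <- pmin(floor(ys), nrow(raster) - 2); fy <- ys - y0
  x0 <- pmin(floor(xs), ncol(raster) - 2); fx <- xs - x0
  # Expand to full H x W index/weight grids (rows vary with y, cols with x).
  Y0 <- matrix(y0 + 1, H, W); FY <- matrix(fy, H, W)
  X0 <- matrix(x0 + 1, H, W, byrow = TRUE); FX <- matrix(fx, H, W, byrow = TRUE)
  v00 <- raster[cbind(as.vector(Y0), as.vector(X0))]
  v01 <- raster[cbind(as.vector(Y0), as.vector(X0) + 1L)]
  v10 <- raster[cbind(as.vector(Y0) + 1L, as.vector(X0))]
  v11 <- raster[cbind(as.vector(Y0) + 1L, as.vector(X0) + 1L)]
  w <- as.vector((1 - FY) * (1 - FX)) * v00 + as.vector((1 - FY) * FX) * v01 +
    as.vector(FY * (1 - FX)) * v10 + as.vector(FY * FX) * v11
  matrix(w, H, W)
}

#' Nearest-neighbor binary-mask resizing
#'
#' Resamples a 0/1 mask to `target_dims` by nearest-neighbor lookup under
#' the same corner-aligned mapping as [resize_bilinear()], so the output
#' stays strictly binary.
#'
#' @param mask A 0/1 matrix.
#' @param target_dims Integer `c(H, W)`.
#' @return A strictly binary `target_dims[1] x target_dims[2]` matrix.
#' @export
resize_mask <- function(mask, target_dims) {
  mask <- check_binary_mask(mask, "mask")
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 2L || any(target_dims < 1L))
    stop("`target_dims` must be two integers >= 1", call. = FALSE)
  if (identical(target_dims, dim(mask))) return(mask)
  ri <- floor(resample_coords(nrow(mask), target_dims[1]) + 0.5) + 1L
  ci <- floor(resample_coords(ncol(mask), target_dims[2]) + 0.5) + 1L
  mask[ri, ci, drop = FALSE]
}

#' Fuse a thermal grid with a plant mask into a Leaf Temperature Map
#'
#' Crosses the scanned thermal map with the plant segmentation pixel by
#' pixel: the thermal raster is bilinearly resized and the mask
#' nearest-neighbor resized to a common target geometry, and each output
#' pixel holds the resized object temperature where the mask marks plant and
#' `NA` elsewhere.  `NA` (not 0 deg C) is the no-plant sentinel, since 0 is
#' a legal temperature.
#'
#' @param grid A `"thermal_grid"`.
#' @param mask A 0/1 plant mask (any dimensions).
#' @param target_dims Integer `c(H, W)` of the fused map; the default
#'   620 x 1280 matches a full-bench map at the working resolution.
#' @return An object of class `"leaf_temperature_map"`: list with `t_l`
#'   (`H x W` matrix, `NA` off-plant), `mask` (resized 0/1 matrix),
#'   `t_a`, `rh`, `grid_dims`, `mask_dims`.
#' @export
build_ltm <- function(grid, mask, target_dims = c(620L, 1280L)) {
  stopifnot(inherits(grid, "thermal_grid"))
  mask <- check_binary_mask(mask, "mask")
  thermal <- resize_bilinear(grid$t_o, target_dims)
  m <- resize_mask(mask, target_dims)
  t_l <- thermal
  t_l[m == 0L] <- NA_real_
  structure(list(t_l = t_l, mask = m, t_a = grid$t_a, rh = grid$rh,
                 grid_dims = c(grid$ny, grid$nx), mask_dims = dim(mask),
                 timestamp = grid$timestamp),
            class = "leaf_temperature_map")
}

#' @export
print.leaf_temperature_map <- function(x, ...) {
  n <- sum(!is.na(x$t_l))
  cat(sprintf("<leaf_temperature_map> %d x %d px, %d plant px (%.1f%%)\n",
              nrow(x$t_l), ncol(x$t_l), n, 100 * n / length(x$t_l)))
  if (n > 0)
    cat(sprintf("  T_L %.2f..%.2f degC, scan T_A %.1f degC\n",
                min(x$t_l, na.rm = TRUE), max(x$t_l, na.rm = TRUE), x$t_a))
  invisible(x)
}

#' Validate a Leaf Temperature Map against a reference raster
#'
#' Compares the fused map `S` with a co-registered reference temperature
#' raster `C` (e.g. a thermal-camera image) pixel by pixel over the plant
#' (non-`NA`) pixels.  The per-pixel error is relative,
#' `(S - C) / C`; the general mean error is the arithmetic mean of the
#' per-pixel errors and the mean standard error is `sd(errors) / sqrt(n)`.
#' Because the relative form is undefined at 0 deg C reference pixels,
#' those are excluded with a logged count, and the plain mean temperature
#' difference `mean(S - C)` in deg C is reported alongside.
#'
#' @param ltm A [build_ltm()] result.
#' @param reference A numeric reference raster of the same dimensions.
#' @return An object of class `"validation_report"`: list with `errors`
#'   (per-pixel relative errors), `general_mean_error`,
#'   `mean_standard_error`, `mean_difference_c` (deg C), `n`, `n_excluded`.
#' @export
validate_against_reference <- function(ltm, reference) {
  stopifnot(inherits(ltm, "leaf_temperature_map"))
  check_raster(reference, "reference")
  if (!identical(dim(reference), dim(ltm$t_l)))
    stop("reference raster dimensions differ from the map", call. = FALSE)
  idx <- which(!is.na(ltm$t_l))
  s <- ltm$t_l[idx]
  c_ <- reference[idx]
  zero <- c_ == 0
  n_excluded <- sum(zero)
  s <- s[!zero]; c_ <- c_[!zero]
  n <- length(s)
  if (n == 0) stop("no comparable plant pixels", call. = FALSE)
  errors <- (s - c_) / c_
  structure(list(errors = errors,
                 general_mean_error = mean(errors),
                 mean_standard_error = stats::sd(errors) / sqrt(n),
                 mean_difference_c = mean(s - c_),
                 n = n, n_excluded = n_excluded),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> n = %d plant px (%d excluded at 0 degC)\n",
                     "  general mean error %.4g, mean standard error %.4g,",
                     " mean difference %.4g degC\n"),
              x$n, x$n_excluded, x$general_mean_error,
              x$mean_standard_error, x$mean_difference_c))
  invisible(x)
}
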