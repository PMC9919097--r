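#' Wet/dry reference surface temperatures
#'
#' Scan-level empirical CWSI limits: the temperature of a water-sprayed leaf
#' (maximal transpiration, the coolest a leaf can be) and of a
#' petroleum-jelly-coated leaf (no transpiration, the warmest).
#'
#' @param t_wet Wet-reference temperature (deg C).
#' @param t_dry Dry-reference temperature (deg C); must exceed `t_wet`.
#' @return An object of class `"reference_temperatures"`.
#' @export
reference_temperatures <- function(t_wet, t_dry) {
  check_scalar(t_wet, "t_wet")
  check_scalar(t_dry, "t_dry")
  if (t_dry <= t_wet)
    stop("`t_dry` must exceed `t_wet`", call. = FALSE)
  structure(list(t_wet = t_wet, t_dry = t_dry),
            class = "reference_temperatures")
}

#' CWSI from baseline limits
#'
#' Normalizes the leaf-air temperature difference between the
#' non-water-stressed lower limit and the non-transpiring upper limit.  The
#' default (canonical) form is `(dT - LL) / (UL - LL)`, for which the anchor
#' identities hold exactly: a plant at the lower limit scores 0 (no water
#' restriction) and one at the upper limit scores 1 (no transpiration).
#' `denominator = "literal"` exposes the variant `(dT - LL) / (UL - dT)`
#' for comparison; it shares the zero anchor but diverges near the upper
#' limit.
#'
#' @param dt Leaf-air temperature difference(s) `T_L - T_A` (deg C),
#'   vectorized.
#' @param ll,ul Lower and upper limits (deg C), `ul > ll`.
#' @param denominator `"range"` (canonical) or `"literal"`.
#' @return Unclipped CWSI value(s); see [clip_cwsi()].
#' @export
cwsi_nwsb <- function(dt, ll, ul, denominator = c("range", "literal")) {
  denominator <- match.arg(denominator)
  check_scalar(ll, "ll")
  check_scalar(ul, "ul")
  if (ul <= ll)
    stop("degenerate limits: `ul` must exceed `ll`", call. = FALSE)
  if (denominator == "range") (dt - ll) / (ul - ll) else (dt - ll) / (ul - dt)
}

#' CWSI from wet/dry reference surfaces
#'
#' Empirical two-reference normalization
#' `(T_L - T_wet) / (T_dry - T_wet)`: 0 at the fully transpiring wet
#' reference, 1 at the non-transpiring dry reference.
#'
#' @param t_l Leaf temperature(s) in deg C, vectorized.
#' @param refs A [reference_temperatures()] pair.
#' @return Unclipped CWSI value(s).
#' @export
cwsi_empirical <- function(t_l, refs) {
  stopifnot(inherits(refs, "reference_temperatures"))
  (t_l - refs$t_wet) / (refs$t_dry - refs$t_wet)
}

#' Clip CWSI values to the index range
#'
#' Out-of-range values arise when the baseline normalization window is
#' displaced from the actual leaf-temperature range; negative values are
#' raised to 0 and values above 1 reduced to the index limit.  The counts of
#' clipped values are attached as attributes `n_below` and `n_above`
#' (`NA` entries are passed through and not counted).
#'
#' @param x Numeric CWSI value(s); non-`NA` entries must be finite.
#' @return Clipped values in `[0, 1]` with clip-count attributes.
#' @export
clip_cwsi <- function(x) {
  if (any(is.infinite(x) | is.nan(x)))
    stop("non-finite CWSI value cannot be clipped", call. = FALSE)
  out <- clamp(x, 0, 1)
  attr(out, "n_below") <- sum(x < 0, na.rm = TRUE)
  attr(out, "n_above") <- sum(x > 1, na.rm = TRUE)
  out
}

#' Per-pixel CWSI map from a Leaf Temperature Map
#'
#' Computes `dT = T_L - T_A` at every plant pixel and normalizes it with
#' scan-level limits: under `method = "nwsb"` the lower limit is the
#' baseline at the current `vpd(t_a, rh)` and the upper limit the
#' potential-VPD construction at `t_a`; under `method = "empirical"` the
#' limits come from wet/dry reference surfaces.  Values are clipped to
#' `[0, 1]` with clip counts recorded; off-plant pixels stay `NA`.
#'
#' @param ltm A [build_ltm()] result with at least one plant pixel.
#' @param t_a Ambient temperature at scan time (deg C); defaults to the
#'   map's scan metadata.
#' @param method `"nwsb"` or `"empirical"`.
#' @param model A [fit_nwsb()] model (required for `"nwsb"`).
#' @param rh Relative humidity at scan time (fraction; required for
#'   `"nwsb"`).
#' @param refs A [reference_temperatures()] pair (required for
#'   `"empirical"`).
#' @param denominator Passed to [cwsi_nwsb()].
#' @param date Optional scan date, metadata.
#' @return An object of class `"stress_map"`: list with `cwsi` (`H x W`
#'   matrix, `NA` off-plant, values in `[0, 1]`), `method`, `n_below`,
#'   `n_above`, `ll`, `ul` (dT-scale limits), `t_a`, `rh`, `date`.
#' @export
stress_map <- function(ltm, t_a = ltm$t_a, method = c("nwsb", "empirical"),
                       model = NULL, rh = ltm$rh, refs = NULL,
                       denominator = c("range", "literal"), date = NULL) {
  stopifnot(inherits(ltm, "leaf_temperature_map"))
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  if (!any(!is.na(ltm$t_l)))
    stop("the leaf temperature map has no plant pixels", call. = FALSE)
  check_scalar(t_a, "t_a")
  if (method == "nwsb") {
    if (is.null(model) || !inherits(model, "nwsb_model"))
      stop("method \"nwsb\" requires a fitted `model`", call. = FALSE)
    if (is.null(rh) || is.na(rh))
      stop("method \"nwsb\" requires `rh` at scan time", call. = FALSE)
    ll <- lower_limit(model, vpd(t_a, rh))
    ul <- upper_limit(model, t_a)
    if (ul <= ll)
      stop(sprintf(paste0("degenerate limits from the baseline (LL = %.3f, ",
                          "UL = %.3f degC at T_A = %.1f, RH = %.2f)"),
                   ll, ul, t_a, rh), call. = FALSE)
    raw <- cwsi_nwsb(ltm$t_l - t_a, ll, ul, denominator = denominator)
  } else {
    if (is.null(refs) || !inherits(refs, "reference_temperatures"))
      stop("method \"empirical\" requires `refs`", call. = FALSE)
    ll <- refs$t_wet - t_a
    ul <- refs$t_dry - t_a
    raw <- cwsi_empirical(ltm$t_l, refs)
  }
  clipped <- clip_cwsi(raw)
  cwsi <- matrix(as.numeric(clipped), nrow(ltm$t_l), ncol(ltm$t_l))
  structure(list(cwsi = cwsi, method = method,
                 n_below = attr(clipped, "n_below"),
                 n_above = attr(clipped, "n_above"),
                 ll = ll, ul = ul, t_a = t_a,
                 rh = if (method == "nwsb") rh else NA_real_,
                 date = date),
            class = "stress_map")
}

#' @export
print.stress_map <- function(x, ...) {
  n <- sum(!is.na(x$cwsi))
  cat(sprintf("<stress_map> %d x %d px (%s method), %d plant px\n",
              nrow(x$cwsi), ncol(x$cwsi), x$method, n))
  cat(sprintf("  CWSI mean %.4f (clipped: %d below 0, %d above 1)\n",
              mean(x$cwsi, na.rm = TRUE), x$n_below, x$n_above))
  invisible(x)
}

#' Per-treatment summary of a stress map
#'
#' Summarizes CWSI over the non-`NA` (plant) pixels of each treatment
#' region.  Regions must partition the map columns; a region with no plant
#' pixels is reported as empty rather than erroring.
#'
#' @param smap A [stress_map()] result (or a plain CWSI matrix).
#' @param layout Named list of column-index vectors, one per treatment,
#'   jointly partitioning the columns (as in a scene's
#'   `treatment_layout`).
#' @param vwc Optional per-treatment volumetric water content (fraction of
#'   field capacity) to attach for joint reporting.
#' @return A data.frame with one row per treatment: `treatment`,
#'   `n_pixels`, `mean_cwsi`, `min_cwsi`, `max_cwsi`, and `vwc` when
#'   supplied.
#' @export
treatment_summary <- function(smap, layout, vwc = NULL) {
  cwsi <- if (inherits(smap, "stress_map")) smap$cwsi else smap
  check_raster(cwsi, "smap")
  cols <- sort(unlist(layout, use.names = FALSE))
  if (!identical(as.integer(cols), seq_len(ncol(cwsi))))
    stop("`layout` must partition the map columns (disjoint cover)",
         call. = FALSE)
  if (!is.null(vwc)) stopifnot(length(vwc) == length(layout))
  rows <- lapply(seq_along(layout), function(k) {
    vals <- cwsi[, layout[[k]], drop = FALSE]
    vals <- vals[!is.na(vals)]
    data.frame(treatment = names(layout)[k],
               n_pixels = length(vals),
               mean_cwsi = if (length(vals)) mean(vals) else NA_real_,
               min_cwsi = if (length(vals)) min(vals) else NA_real_,
               max_cwsi = if (length(vals)) max(vals) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(vwc)) out$vwc <- vwc
  out
}
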