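#' Generate a diurnal ambient temperature / humidity series
#'
#' Sinusoidal diurnal cycles (temperature peaking mid-afternoon, humidity in
#' anti-phase) plus Gaussian noise, sampled on a fixed cadence.  Thirty days
#' at the default 10-minute cadence gives 4320 records, the series length
#' used to parameterize the non-water-stressed baseline over one crop cycle.
#'
#' @param days Number of days (>= 1).
#' @param cadence_min Sampling interval in minutes.
#' @param t_a_mean,t_a_amplitude Mean and diurnal amplitude of ambient
#'   temperature (deg C).
#' @param rh_mean,rh_amplitude Mean and diurnal amplitude of relative
#'   humidity (fraction); the series is clipped to `[0, 1]`.
#' @param t_a_noise_sd,rh_noise_sd Gaussian noise standard deviations.
#' @param seed Optional integer seed.
#' @param start Start date (`Date`, `POSIXct`, or string), midnight UTC.
#' @return A data.frame with columns `timestamp` (POSIXct, UTC, strictly
#'   increasing), `t_a` (deg C) and `rh` (fraction in `[0, 1]`).
#' @export
generate_environment_series <- function(days = 30, cadence_min = 10,
                                        t_a_mean = 22, t_a_amplitude = 4,
                                        rh_mean = 0.60, rh_amplitude = 0.15,
                                        t_a_noise_sd = 0.3, rh_noise_sd = 0.03,
                                        seed = NULL, start = "2020-05-25") {
  check_scalar(days, "days", lower = 1)
  check_scalar(cadence_min, "cadence_min", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(days * 24 * 60 / cadence_min))
  t0 <- as.POSIXct(paste(as.Date(start), "00:00:00"), tz = "UTC")
  timestamp <- t0 + (seq_len(n) - 1L) * cadence_min * 60
  hour <- (as.numeric(timestamp - t0, units = "hours")) %% 24
  phase <- sin(2 * pi * (hour - 8) / 24)  # peak at 14:00, trough at 02:00
  t_a <- t_a_mean + t_a_amplitude * phase +
    if (t_a_noise_sd > 0) stats::rnorm(n, 0, t_a_noise_sd) else 0
  rh <- rh_mean - rh_amplitude * phase +
    if (rh_noise_sd > 0) stats::rnorm(n, 0, rh_noise_sd) else 0
  data.frame(timestamp = timestamp, t_a = t_a, rh = clamp(rh, 0, 1))
}

#' Generate paired (T_L - T_A, VPD) baseline observations
#'
#' Simulates the fixed-point leaf-temperature sensor used to parameterize
#' the non-water-stressed baseline: for every environment record the vapor
#' pressure deficit is computed from `t_a` and `rh`, and the leaf-air
#' temperature difference is drawn from the linear model
#' `dT = a + b * VPD + N(0, noise_sd)`.
#'
#' @param env An environment series from [generate_environment_series()].
#' @param a,b True intercept (deg C) and slope (deg C / kPa).
#' @param noise_sd Gaussian observation noise (deg C).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `timestamp`, `vpd` (kPa), `dt` (deg C).
#' @seealso [fit_nwsb()]
#' @export
generate_nwsb_observations <- function(env, a = 2.54, b = -1.71,
                                       noise_sd = 0.3, seed = NULL) {
  stopifnot(is.data.frame(env), nrow(env) > 0,
            all(c("timestamp", "t_a", "rh") %in% names(env)))
  if (!is.null(seed)) set.seed(seed)
  v <- vpd(env$t_a, env$rh)
  dt <- a + b * v +
    if (noise_sd > 0) stats::rnorm(nrow(env), 0, noise_sd) else 0
  data.frame(timestamp = env$timestamp, vpd = v, dt = dt)
}

#' Simulate threshold-triggered soil-moisture traces for three treatments
#'
#' Volumetric water content (VWC), normalized to field capacity (FC), dries
#' down linearly with small Gaussian jitter; whenever a treatment's trace
#' falls to or below its critical threshold an irrigation event of fixed
#' volume is logged and the trace is recharged by a fixed fraction of FC.
#' The default thresholds 0.85 / 0.75 / 0.55 of FC define treatments T1-T3
#' with increasing imposed water stress.
#'
#' @param days Simulated cycle length (days).
#' @param cadence_min Sensor reading interval (minutes).
#' @param thresholds Length-3 critical VWC thresholds (fractions of FC in
#'   `(0, 1)`), one per treatment.
#' @param start_vwc Initial VWC (fraction of FC), scalar or one per
#'   treatment.  The default `NULL` starts each trace at its own
#'   post-irrigation level (`threshold + recharge`), i.e. with treatments
#'   already in their irrigation regimes when monitoring begins.
#' @param drydown_per_day Linear drydown rate (FC fraction per day); a rate
#'   of 0 gives a flat trace with no irrigation events.
#' @param recharge VWC recharge per irrigation event (fraction of FC).
#' @param noise_sd Per-reading Gaussian jitter (fraction of FC).
#' @param irrigation_volume_l Applied volume per event (liters, metadata).
#' @param seed Optional integer seed.
#' @param start Start date, midnight UTC.
#' @return An object of class `"moisture_series"`: list with `readings`
#'   (data.frame `timestamp`, `treatment`, `vwc`), `events` (data.frame
#'   `timestamp`, `treatment`, `volume_l`), `thresholds`, `cadence_min`.
#' @export
simulate_soil_moisture <- function(days = 30, cadence_min = 20,
                                   thresholds = c(0.85, 0.75, 0.55),
                                   start_vwc = NULL, drydown_per_day = 0.04,
                                   recharge = 0.12, noise_sd = 0.005,
                                   irrigation_volume_l = 0.7,
                                   seed = NULL, start = "2020-05-25") {
  check_scalar(days, "days", lower = 1)
  stopifnot(length(thresholds) == 3L)
  for (th in thresholds)
    check_scalar(th, "thresholds", lower = 0, upper = 1,
                 strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(drydown_per_day, "drydown_per_day", lower = 0)
  check_scalar(recharge, "recharge", lower = 0)
  if (is.null(start_vwc)) start_vwc <- thresholds + recharge
  start_vwc <- rep_len(start_vwc, 3L)
  for (sv in start_vwc)
    check_scalar(sv, "start_vwc", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(days * 24 * 60 / cadence_min))
  t0 <- as.POSIXct(paste(as.Date(start), "00:00:00"), tz = "UTC")
  timestamp <- t0 + seq_len(n) * cadence_min * 60
  dt_days <- cadence_min / (24 * 60)
  readings <- vector("list", 3L)
  events <- vector("list", 3L)
  for (k in 1:3) {
    v <- numeric(n)
    ev <- integer(0)
    cur <- start_vwc[k]
    jit <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    for (i in seq_len(n)) {
      cur <- max(cur - drydown_per_day * dt_days, 1e-6)
      # jitter is sensor read noise: it perturbs the reading (and hence the
      # irrigation trigger), not the water balance itself
      obs <- max(cur + jit[i], 1e-6)
      v[i] <- obs
      if (obs <= thresholds[k]) {
        ev <- c(ev, i)
        cur <- cur + recharge
      }
    }
    readings[[k]] <- data.frame(timestamp = timestamp,
                                treatment = paste0("T", k), vwc = v)
    events[[k]] <- data.frame(timestamp = timestamp[ev],
                              treatment = rep(paste0("T", k), length(ev)),
                              volume_l = rep(irrigation_volume_l, length(ev)))
  }
  structure(list(readings = do.call(rbind, readings),
                 events = do.call(rbind, events),
                 thresholds = thresholds, cadence_min = cadence_min),
            class = "moisture_series")
}

#' @export
print.moisture_series <- function(x, ...) {
  cat(sprintf("<moisture_series> %d readings x 3 treatments, %d irrigation events\n",
              nrow(x$readings) / 3L, nrow(x$events)))
  cat(sprintf("  thresholds %s of field capacity, cadence %d min\n",
              paste(x$thresholds, collapse = "/"), as.integer(x$cadence_min)))
  invisible(x)
}
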