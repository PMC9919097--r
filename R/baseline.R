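#' Saturation vapor pressure of air
#'
#' Tetens-form closed expression
#' `es(T) = 0.6108 * 10^(7.5 T / (273.3 + T))` in kPa, valid for
#' `T > -273.3` deg C.
#'
#' @param t Air temperature in deg C (vectorized).
#' @return Saturation vapor pressure in kPa.
#' @examples
#' saturation_vp(0)     # 0.6108 kPa
#' saturation_vp(22.1)  # ~2.22 kPa
#' @export
saturation_vp <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  if (any(t <= -273.3))
    stop("`t` must be greater than -273.3 degC", call. = FALSE)
  0.6108 * 10^(7.5 * t / (273.3 + t))
}

#' Vapor pressure deficit
#'
#' `VPD = (1 - RH) * es(T_A)` in kPa.  Relative humidity must be a fraction
#' in `[0, 1]`; a percent value (> 1) is rejected rather than silently
#' rescaled, to avoid unit mistakes.
#'
#' @param t_a Ambient temperature, deg C (vectorized).
#' @param rh Relative humidity as a fraction in `[0, 1]` (vectorized).
#' @return Vapor pressure deficit in kPa.
#' @examples
#' vpd(22.1, 0.47)  # ~1.18 kPa
#' vpd(25, 1)       # saturated air -> 0
#' @export
vpd <- function(t_a, rh) {
  if (!is.numeric(rh) || any(!is.finite(rh)))
    stop("`rh` must be finite numeric", call. = FALSE)
  if (any(rh < 0 | rh > 1))
    stop("`rh` must be a fraction in [0, 1]; percent values are not ",
         "rescaled automatically", call. = FALSE)
  (1 - rh) * saturation_vp(t_a)
}

#' Fit the Non-Water-Stressed Baseline
#'
#' Ordinary least squares of the leaf-air temperature difference on vapor
#' pressure deficit, `dT = a + b * VPD`, fitted on observations from
#' well-watered plants.  Residual diagnostics are attached: the residual
#' mean (identically 0 for a fit with intercept), the slope of residuals on
#' fitted values (a bias check, also identically 0 under OLS), and a
#' Breusch-Pagan test as the variance-homogeneity summary.
#'
#' @param dt Numeric vector of `T_L - T_A` values (deg C).
#' @param vpd Numeric vector of vapor pressure deficits (kPa), same length,
#'   not constant.
#' @param env_tag `"protected"` (indoor/greenhouse) or `"unprotected"`
#'   (open-air) parameterization environment.
#' @return An object of class `"nwsb_model"`: list with `a`, `b`, `n`,
#'   `se_a`, `se_b`, `r_squared`, `sigma`, `residuals`, `diagnostics`
#'   (list `residual_mean`, `resid_fitted_slope`, `bp_statistic`,
#'   `bp_p_value`), `env_tag`.
#' @export
fit_nwsb <- function(dt, vpd, env_tag = c("protected", "unprotected")) {
  env_tag <- match.arg(env_tag)
  if (length(dt) != length(vpd))
    stop("`dt` and `vpd` must have the same length", call. = FALSE)
  n <- length(dt)
  if (n < 3L) stop("insufficient data: need at least 3 points", call. = FALSE)
  if (stats::sd(vpd) == 0)
    stop("`vpd` is constant: the baseline slope is not identifiable",
         call. = FALSE)
  fit <- stats::lm(dt ~ vpd, data = data.frame(dt = dt, vpd = vpd))
  # noiseless interpolation is a legitimate input; silence only the
  # perfect-fit caveat from summary.lm
  quiet_perfect <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- quiet_perfect(summary(fit))
  res <- stats::residuals(fit)
  bias_fit <- quiet_perfect(stats::lm(res ~ stats::fitted(fit)))
  bp <- lmtest::bptest(fit)
  structure(list(
    a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
    n = n,
    se_a = sm$coefficients[1, 2], se_b = sm$coefficients[2, 2],
    r_squared = sm$r.squared, sigma = sm$sigma,
    residuals = res,
    diagnostics = list(residual_mean = mean(res),
                       resid_fitted_slope = unname(stats::coef(bias_fit)[2]),
                       bp_statistic = unname(bp$statistic),
                       bp_p_value = unname(bp$p.value)),
    env_tag = env_tag
  ), class = "nwsb_model")
}

#' @export
print.nwsb_model <- function(x, ...) {
  cat(sprintf("<nwsb_model> dT = %.3f %+.3f * VPD  (degC, kPa; %s environment)\n",
              x$a, x$b, x$env_tag))
  cat(sprintf("  n = %d, se(a) = %.3g, se(b) = %.3g, R^2 = %.3f\n",
              x$n, x$se_a, x$se_b, x$r_squared))
  invisible(x)
}

#' Lower temperature-difference limit of the CWSI
#'
#' Evaluates the baseline at the ambient vapor pressure deficit at reading
#' time: `(T_L - T_A)_LL = a + b * vpd_now`, the temperature difference of a
#' fully transpiring plant under the current conditions.  At `vpd_now = 0`
#' this is the intercept `a`.
#'
#' @param model A fitted [fit_nwsb()] model.
#' @param vpd_now Current vapor pressure deficit (kPa, >= 0).
#' @return Lower limit in deg C.
#' @export
lower_limit <- function(model, vpd_now) {
  stopifnot(inherits(model, "nwsb_model"))
  if (any(vpd_now < 0)) stop("`vpd_now` must be >= 0", call. = FALSE)
  model$a + model$b * vpd_now
}

#' Upper temperature-difference limit of the CWSI
#'
#' Potential-VPD construction of the non-transpiring limit: the baseline is
#' extrapolated to the vapor-pressure gradient that would remain if the air
#' at ambient temperature were saturated,
#' `VPD_pot = es(T_A) - es(T_A + a)` (non-positive for `a > 0`), giving
#' `(T_L - T_A)_UL = a + b * VPD_pot`.  With the usual signs (`a > 0`,
#' `b < 0`) the upper limit exceeds the lower limit at every VPD, keeping
#' the CWSI denominator positive.
#'
#' @param model A fitted [fit_nwsb()] model.
#' @param t_a Ambient temperature at reading time (deg C).
#' @return Upper limit in deg C.
#' @export
upper_limit <- function(model, t_a) {
  stopifnot(inherits(model, "nwsb_model"))
  pot <- saturation_vp(t_a) - saturation_vp(t_a + model$a)
  model$a + model$b * pot
}
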