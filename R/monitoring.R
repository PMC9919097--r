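#' Exponentially Weighted Moving Average control chart
#'
#' Smooths a series with `z_t = lambda * x_t + (1 - lambda) * z_{t-1}`,
#' `z_0` at the process center, and draws variance-adjusted control limits
#' `center +/- L * sigma * sqrt(lambda / (2 - lambda) * (1 - (1 - lambda)^(2t)))`
#' which widen monotonically toward their asymptote.  Points of `z` beyond
#' the limits are flagged as out of control.  The EWMA chart is robust to
#' non-normal data, which suits irregular stress and moisture series.
#'
#' Defaults `lambda = 0.2`, `L = 3` follow standard control-chart practice;
#' the center defaults to the sample mean and `sigma` to the sample
#' standard deviation of the raw series.
#'
#' @param x Numeric series, length >= 2.
#' @param lambda Smoothing weight in `(0, 1]`; 1 disables smoothing.
#' @param L Control-limit width in multiples of sigma.
#' @param center Process target; default `mean(x)`.
#' @param sigma Process standard deviation; default `sd(x)` (a constant
#'   series then triggers a zero-width-limits warning).
#' @return An object of class `"ewma_chart"`: list with `x`, `z`, `ucl`,
#'   `lcl` (per-point limits), `center`, `sigma`, `lambda`, `L`,
#'   `violations` (indices with `z` beyond the limits).
#' @examples
#' ch <- ewma_chart(c(2, 4), lambda = 0.5, center = 0, sigma = 1)
#' ch$z  # 1, 2.5
#' @export
ewma_chart <- function(x, lambda = 0.2, L = 3, center = NULL, sigma = NULL) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("`x` must be a numeric series of length >= 2", call. = FALSE)
  check_scalar(lambda, "lambda", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(L, "L", lower = 0)
  n <- length(x)
  if (is.null(center)) center <- mean(x)
  if (is.null(sigma)) {
    sigma <- stats::sd(x)
    if (sigma == 0)
      warning("constant series: control limits have zero width", call. = FALSE)
  }
  z <- numeric(n)
  prev <- center
  for (t in seq_len(n)) {
    prev <- lambda * x[t] + (1 - lambda) * prev
    z[t] <- prev
  }
  t_idx <- seq_len(n)
  half_width <- L * sigma *
    sqrt(lambda / (2 - lambda) * (1 - (1 - lambda)^(2 * t_idx)))
  ucl <- center + half_width
  lcl <- center - half_width
  violations <- which(z > ucl | z < lcl)
  structure(list(x = x, z = z, ucl = ucl, lcl = lcl, center = center,
                 sigma = sigma, lambda = lambda, L = L,
                 violations = violations),
            class = "ewma_chart")
}

#' @export
print.ewma_chart <- function(x, ...) {
  cat(sprintf("<ewma_chart> n = %d, lambda = %.2f, L = %.1f, center = %.4g\n",
              length(x$z), x$lambda, x$L, x$center))
  cat(sprintf("  %d point(s) out of control\n", length(x$violations)))
  invisible(x)
}

#' In-control stability verdict of an EWMA chart
#'
#' A process is stable exactly when no smoothed point lies outside the
#' control limits; any excursion makes it unstable.
#'
#' @param chart An [ewma_chart()].
#' @return An object of class `"stability_verdict"`: list with `stable`
#'   (logical), `n_violations`, `first_violation_index` (`NA` if stable).
#' @export
is_stable <- function(chart) {
  stopifnot(inherits(chart, "ewma_chart"))
  nv <- length(chart$violations)
  structure(list(stable = nv == 0L, n_violations = nv,
                 first_violation_index = if (nv) chart$violations[1] else NA_integer_),
            class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  if (x$stable) cat("<stability_verdict> stable: no points beyond the control limits\n")
  else cat(sprintf("<stability_verdict> unstable: %d violation(s), first at index %d\n",
                   x$n_violations, x$first_violation_index))
  invisible(x)
}

#' Joint EWMA report for CWSI and soil-moisture cycle series
#'
#' Builds one EWMA chart per treatment for the daily mean CWSI and one for
#' the normalized soil moisture (six charts for three treatments), plus the
#' Spearman rank correlation between each treatment's CWSI and moisture
#' series — expected negative, since stress rises as soil water falls.
#'
#' @param cwsi_series Data.frame with columns `day`, `treatment`, `value`
#'   (daily mean CWSI).
#' @param vwc_series Data.frame with the same columns and identical
#'   day/treatment index (normalized VWC, fraction of field capacity).
#' @param lambda,L Chart parameters, passed to [ewma_chart()].
#' @return An object of class `"cycle_report"`: list with `charts` (named
#'   list `cwsi_<treatment>` / `vwc_<treatment>`), `correlations`
#'   (data.frame `treatment`, `spearman`), `stable` (all charts in
#'   control).
#' @export
joint_cycle_report <- function(cwsi_series, vwc_series, lambda = 0.2, L = 3) {
  need <- c("day", "treatment", "value")
  stopifnot(is.data.frame(cwsi_series), is.data.frame(vwc_series),
            all(need %in% names(cwsi_series)), all(need %in% names(vwc_series)))
  treatments <- sort(unique(cwsi_series$treatment))
  if (!identical(treatments, sort(unique(vwc_series$treatment))))
    stop("treatment sets of the two series differ (alignment error)",
         call. = FALSE)
  charts <- list()
  cors <- vector("list", length(treatments))
  for (k in seq_along(treatments)) {
    tr <- treatments[k]
    a <- cwsi_series[cwsi_series$treatment == tr, ]
    b <- vwc_series[vwc_series$treatment == tr, ]
    a <- a[order(a$day), ]; b <- b[order(b$day), ]
    if (!identical(as.numeric(a$day), as.numeric(b$day)))
      stop("day indices are misaligned for treatment ", tr,
           " (alignment error)", call. = FALSE)
    charts[[paste0("cwsi_", tr)]] <- ewma_chart(a$value, lambda, L)
    charts[[paste0("vwc_", tr)]] <- ewma_chart(b$value, lambda, L)
    cors[[k]] <- data.frame(treatment = tr,
                            spearman = stats::cor(a$value, b$value,
                                                  method = "spearman"))
  }
  structure(list(charts = charts,
                 correlations = do.call(rbind, cors),
                 stable = all(vapply(charts, function(ch)
                   is_stable(ch)$stable, logical(1)))),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle_report> %d EWMA charts, process %s\n", length(x$charts),
              if (x$stable) "stable" else "unstable"))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
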