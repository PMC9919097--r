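#' Excess-green index of an RGB image
#'
#' Computes the ExG vegetation index on chromaticity-normalized channels:
#' with `s = R + G + B`, `r = R/s`, `g = G/s`, `b = B/s`,
#' `ExG = 2g - r - b`.  Pure-black pixels (`s = 0`) map to 0, the achromatic
#' limit, so the index is finite everywhere and lies in `[-1, 2]`.  The
#' index is invariant under uniform channel scaling, which makes it robust
#' to illumination differences between soil and canopy.
#'
#' @param rgb An `H x W x 3` numeric array of 8-bit channel intensities.
#' @return An `H x W` matrix of ExG values.
#' @examples
#' excess_green(array(c(0, 255, 0), c(1, 1, 3)))     # pure green -> 2
#' excess_green(array(c(80, 80, 80), c(1, 1, 3)))    # achromatic -> 0
#' @export
excess_green <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("`rgb` must be an H x W x 3 array", call. = FALSE)
  r <- rgb[, , 1, drop = TRUE] * 1.0
  g <- rgb[, , 2, drop = TRUE] * 1.0
  b <- rgb[, , 3, drop = TRUE] * 1.0
  s <- r + g + b
  out <- (2 * g - r - b) / s
  out[s == 0] <- 0
  matrix(out, nrow = dim(rgb)[1], ncol = dim(rgb)[2])
}

#' Otsu threshold of a numeric sample
#'
#' Histogram-based threshold maximizing between-class variance, computed on
#' `n_bins` equal-width bins spanning the observed range of `x`.  Returns
#' the upper edge of the optimal lower-class bin, so classifying by
#' `x > otsu_threshold(x)` reproduces the two Otsu classes.
#'
#' @param x Numeric vector or matrix (finite values).
#' @param n_bins Number of histogram bins.
#' @return The threshold, or `NA` if `x` is constant (single-class input).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  cand <- sb2[-n_bins]
  ks <- which(cand == max(cand))  # ties span empty gaps; take the midpoint
  mean(breaks[ks + 1L])
}

#' Threshold an ExG map into a plant/soil mask
#'
#' Pixels with ExG strictly above the threshold are labeled plant (1), the
#' rest soil (0).  With `method = "otsu"` the threshold maximizes the
#' between-class variance of the ExG histogram (256 bins over the observed
#' range); a constant map yields a single-class warning and an all-soil
#' mask.  With `method = "fixed"` the supplied `threshold` is used.
#'
#' @param exg An ExG matrix from [excess_green()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`.
#' @return An `H x W` 0/1 integer matrix with attribute
#'   `provenance = "predicted"` and attribute `threshold`.
#' @export
segment_exg <- function(exg, method = c("otsu", "fixed"), threshold = NULL) {
  check_raster(exg, "exg")
  if (!all(is.finite(exg))) stop("`exg` must be finite", call. = FALSE)
  method <- match.arg(method)
  if (method == "otsu") {
    threshold <- otsu_threshold(exg)
    if (is.na(threshold)) {
      warning("constant ExG map: single-class input, returning an all-soil mask",
              call. = FALSE)
      mask <- matrix(0L, nrow(exg), ncol(exg))
      attr(mask, "provenance") <- "predicted"
      attr(mask, "threshold") <- NA_real_
      return(mask)
    }
  } else if (is.null(threshold)) {
    stop("`threshold` is required when method = \"fixed\"", call. = FALSE)
  }
  mask <- matrix(as.integer(exg > threshold), nrow(exg), ncol(exg))
  attr(mask, "provenance") <- "predicted"
  attr(mask, "threshold") <- threshold
  mask
}

#' Manual-reference binarization from sampled plant pixels
#'
#' Reproduces the manual labeling procedure used to build reference masks:
#' the mean and standard deviation of each RGB channel are computed over a
#' small set of hand-picked plant pixels (ten in the original protocol), and
#' a pixel is labeled plant (1) exactly when all three of its channel values
#' lie within `mean +/- 1 sd` of the sampled statistics.
#'
#' @param rgb An `H x W x 3` 8-bit array.
#' @param samples A two-column matrix or data.frame of `(row, col)` pixel
#'   coordinates (1-based), at least two, all inside the image.
#' @return An `H x W` 0/1 integer matrix with attribute
#'   `provenance = "reference"`.
#' @export
reference_labeling <- function(rgb, samples) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("`rgb` must be an H x W x 3 array", call. = FALSE)
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L)
    stop("at least two sample pixels are required", call. = FALSE)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  if (any(samples[, 1] < 1 | samples[, 1] > H |
          samples[, 2] < 1 | samples[, 2] > W))
    stop("sample coordinate out of image bounds", call. = FALSE)
  mask <- matrix(TRUE, H, W)
  for (ch in 1:3) {
    vals <- rgb[cbind(samples[, 1], samples[, 2], ch)]
    m <- mean(vals); s <- stats::sd(vals)
    plane <- rgb[, , ch]
    mask <- mask & plane >= m - s & plane <= m + s
  }
  out <- matrix(as.integer(mask), H, W)
  attr(out, "provenance") <- "reference"
  out
}

#' Pixel-wise confusion counts between two binary masks
#'
#' @param pred Predicted 0/1 mask.
#' @param ref Reference 0/1 mask of the same dimensions.
#' @return An object of class `"confusion_counts"`: list with integer
#'   fields `tp`, `fp`, `fn`, `tn` summing to the pixel count.
#' @export
confusion <- function(pred, ref) {
  pred <- check_binary_mask(pred, "pred")
  ref <- check_binary_mask(ref, "ref")
  if (!identical(dim(pred), dim(ref)))
    stop("`pred` and `ref` dimensions differ", call. = FALSE)
  tp <- sum(pred == 1L & ref == 1L)
  fp <- sum(pred == 1L & ref == 0L)
  fn <- sum(pred == 0L & ref == 1L)
  tn <- sum(pred == 0L & ref == 0L)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Segmentation quality metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, their harmonic-mean
#' F-score, accuracy `(TP+TN)/total` and total error `1 - accuracy`.  The
#' F-score grades a classification between 0 (no true positives) and 1
#' (perfect); accordingly the 0/0 cases of precision and sensitivity, and
#' the F-score whenever `TP = 0`, are defined as 0.
#'
#' @param counts A [confusion()] result.
#' @param processing_time Optional wall time in seconds, informational.
#' @return An object of class `"segmentation_metrics"`: list with
#'   `precision`, `sensitivity`, `f_score`, `accuracy`, `total_error`
#'   (fractions in `[0, 1]`) and `processing_time`.
#' @export
segmentation_metrics <- function(counts, processing_time = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  precision <- if (counts$tp + counts$fp == 0) 0 else counts$tp / (counts$tp + counts$fp)
  sensitivity <- if (counts$tp + counts$fn == 0) 0 else counts$tp / (counts$tp + counts$fn)
  f_score <- if (counts$tp == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  accuracy <- (counts$tp + counts$tn) / total
  structure(list(precision = precision, sensitivity = sensitivity,
                 f_score = f_score, accuracy = accuracy,
                 total_error = 1 - accuracy,
                 processing_time = processing_time),
            class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_metrics> precision %.2f%%  sensitivity %.2f%%",
                     "  F-score %.2f%%  accuracy %.2f%%  total error %.2f%%\n"),
              100 * x$precision, 100 * x$sensitivity, 100 * x$f_score,
              100 * x$accuracy, 100 * x$total_error))
  invisible(x)
}
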