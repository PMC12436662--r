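# Enrichment kinetics: drift registration, ROI time series, Gompertz
# fitting, and plate-reader baseline arithmetic.

#' Estimate and correct rigid x-y drift in a movie
#'
#' Per-frame translation relative to a reference frame, estimated by
#' maximizing the cross-correlation (computed by FFT) with subpixel
#' refinement by quadratic interpolation of the correlation peak. Frames
#' are resampled (bilinear) into alignment; pixels carried in from outside
#' the frame are `NA`.
#'
#' @param movie numeric array `[y, x, t]` with at least 2 frames.
#' @param reference index of the reference frame.
#' @param upsample if `FALSE`, shifts are rounded to whole pixels.
#' @return list with `shifts` (t x 2 matrix of `(dy, dx)`, the displacement
#'   of each frame relative to the reference) and `corrected` (aligned
#'   movie).
#' @export
register_translation <- function(movie, reference = 1, upsample = TRUE) {
  stopifnot(length(dim(movie)) == 3, dim(movie)[3] >= 2)
  nt <- dim(movie)[3]
  ref <- movie[, , reference]
  if (sd(ref) == 0) warning("reference frame is featureless; zero shifts")
  fr_ref <- fft(ref)
  shifts <- matrix(0, nt, 2, dimnames = list(NULL, c("dy", "dx")))
  corrected <- movie
  for (t in seq_len(nt)) {
    fr <- movie[, , t]
    if (t != reference && sd(fr) > 0 && sd(ref) > 0) {
      cc <- Re(fft(fft(fr) * Conj(fr_ref), inverse = TRUE))
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      ny <- nrow(cc); nx <- ncol(cc)
      dy <- pk[1] - 1; dx <- pk[2] - 1
      if (dy > ny / 2) dy <- dy - ny
      if (dx > nx / 2) dx <- dx - nx
      if (upsample) {
        wrap <- function(i, n) ((i - 1) %% n) + 1
        py <- pk[1]; px <- pk[2]
        c0 <- cc[py, px]
        cm <- cc[wrap(py - 1, ny), px]; cp <- cc[wrap(py + 1, ny), px]
        den <- cm - 2 * c0 + cp
        if (den != 0) dy <- dy + 0.5 * (cm - cp) / den
        cm <- cc[py, wrap(px - 1, nx)]; cp <- cc[py, wrap(px + 1, nx)]
        den <- cm - 2 * c0 + cp
        if (den != 0) dx <- dx + 0.5 * (cm - cp) / den
      }
      shifts[t, ] <- c(dy, dx)
      corrected[, , t] <- shift_image(fr, -dy, -dx, fill = NA_real_)
    }
  }
  list(shifts = shifts, corrected = corrected)
}

#' ROI mean-intensity time series with enrichment normalization
#'
#' Mean intensity inside the ROI per frame. Normalization follows the
#' enrichment convention: the frame-1 background (mean outside the ROI) is
#' subtracted, then the series is divided by its maximum, so the largest
#' value is 1 when the background is stationary.
#'
#' @param movie numeric array `[y, x, t]` (typically drift-corrected).
#' @param roi logical or 0/1 matrix, nonempty.
#' @param times_min frame times in minutes; defaults to `0, 1, 2, ...`.
#' @param normalize one of `"max"` (divide by the series maximum) or
#'   `"none"`.
#' @param roi_id optional label.
#' @return object of class `enrichment_series`: list with `times_min`,
#'   `values` (normalized), `raw`, `roi_id`.
#' @export
roi_timeseries <- function(movie, roi, times_min = NULL,
                           normalize = c("max", "none"), roi_id = NA) {
  normalize <- match.arg(normalize)
  stopifnot(length(dim(movie)) == 3)
  roi <- as_binary(roi)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  if (!all(dim(roi) == dim(movie)[1:2]))
    stop("ROI shape does not match the movie frames", call. = FALSE)
  nt <- dim(movie)[3]
  raw <- vapply(seq_len(nt), function(t) {
    fr <- movie[, , t]
    v <- fr[roi]
    if (any(is.na(v)))
      stop("ROI leaves the frame after registration", call. = FALSE)
    mean(v)
  }, numeric(1))
  if (is.null(times_min)) times_min <- seq_len(nt) - 1
  if (any(diff(times_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  bg0 <- mean(movie[, , 1][!roi], na.rm = TRUE)
  vals <- raw - bg0
  if (normalize == "max") {
    mx <- max(vals)
    if (mx <= 0) stop("series maximum is not positive after background subtraction",
                      call. = FALSE)
    vals <- vals / mx
  }
  structure(list(times_min = times_min, values = vals, raw = raw,
                 background0 = bg0, roi_id = roi_id),
            class = "enrichment_series")
}

#' Fit the Gompertz growth law to an enrichment series
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `Y(X) = YM * (Y0/YM) ^ exp(-K X)` with positivity bounds.
#' Initialization: `YM` from the series maximum, `Y0` from the first value
#' (floored at 1e-3), `K` from the reciprocal time-to-half-plateau.
#'
#' @param series an `enrichment_series`, or a numeric vector of values.
#' @param times_min times, required when `series` is a plain vector.
#' @return object of class `gompertz_fit`: list with `YM`, `Y0`, `K`,
#'   `one_over_K`, `R2`, `cov` (3x3 covariance of the estimates), and the
#'   underlying `fit`.
#' @export
fit_gompertz <- function(series, times_min = NULL) {
  if (inherits(series, "enrichment_series")) {
    v <- series$values; t <- series$times_min
  } else {
    v <- as.numeric(series); t <- times_min
    if (is.null(t)) stop("times_min required for a plain vector",
                         call. = FALSE)
  }
  if (length(v) < 5) stop("need at least 5 points", call. = FALSE)
  if (diff(range(v)) == 0) stop("values are all equal", call. = FALSE)
  YM0 <- max(v)
  Y00 <- max(v[1], 1e-3)
  half <- (YM0 + Y00) / 2
  i_half <- which(v >= half)[1]
  K0 <- if (!is.na(i_half) && t[i_half] > 0) 1 / t[i_half] else 1 / max(t[t > 0][1], 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ YM * (Y0 / YM)^(exp(-K * t)),
                      data = data.frame(t = t, v = v),
                      start = list(YM = YM0, Y0 = Y00, K = K0),
                      lower = c(YM = 1e-12, Y0 = 1e-12, K = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Gompertz fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- coef(fit)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((v - mean(v))^2)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  structure(list(YM = unname(cf["YM"]), Y0 = unname(cf["Y0"]),
                 K = unname(cf["K"]), one_over_K = 1 / unname(cf["K"]),
                 R2 = 1 - ss_res / ss_tot, cov = vc, fit = fit),
            class = "gompertz_fit")
}

#' @exportS3Method
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("<gompertz_fit> YM = %.4g, Y0 = %.4g, K = %.4g (1/K = %.4g), R2 = %.4f\n",
              x$YM, x$Y0, x$K, x$one_over_K, x$R2))
  invisible(x)
}

#' Scalar baseline correction
#'
#' Elementwise subtraction of a scalar baseline (e.g., the mean
#' fluorescence of the probe in buffer, or the reaction-buffer turbidity).
#'
#' @param values numeric vector.
#' @param baseline scalar baseline.
#' @return corrected vector.
#' @export
baseline_correct <- function(values, baseline) {
  stopifnot(length(baseline) == 1, is.finite(baseline))
  values - baseline
}
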