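# Condensate segmentation and dense/dilute partitioning thermodynamics.

#' Segment condensates by Otsu thresholding after Gaussian smoothing
#'
#' The image is convolved with a Gaussian (default sigma 2 px), thresholded
#' with Otsu's method, and connected components (8-connected) smaller than
#' `min_area_px` are discarded.
#'
#' @param img numeric matrix `[y, x]`, finite and non-constant.
#' @param gaussian_sigma_px Gaussian pre-smoothing sigma, pixels.
#' @param min_area_px minimum component area kept, pixels.
#' @return object of class `segmentation_result`: a list with `labels`
#'   (integer label matrix, 0 = background, ids consecutive) and `regions`
#'   (data.frame: `region_id`, centroid `y`/`x` in px, `area_px2`,
#'   `mean_intensity`, `max_intensity`, `min_intensity`). Intensities are
#'   measured on the unsmoothed input.
#' @export
segment_condensates <- function(img, gaussian_sigma_px = 2,
                                min_area_px = 20) {
  stop_if_not_matrix(img)
  smoothed <- if (gaussian_sigma_px > 0)
    as_plain_matrix(EBImage::gblur(EBImage::Image(img), sigma = gaussian_sigma_px))
  else img
  thr <- otsu_threshold(smoothed)
  mask <- smoothed > thr
  labels <- label_components(mask)
  regions <- region_props(labels, img)
  keep <- regions$region_id[regions$area_px2 >= min_area_px]
  labels[!(labels %in% keep)] <- 0L
  # relabel consecutively
  if (length(keep)) {
    labels[labels > 0] <- match(labels[labels > 0], sort(keep))
  }
  regions <- region_props(labels, img)
  structure(list(labels = labels, regions = regions,
                 threshold = thr, gaussian_sigma_px = gaussian_sigma_px,
                 min_area_px = min_area_px),
            class = "segmentation_result")
}

#' @exportS3Method
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>", nrow(x$regions), "regions, threshold",
      signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Per-condensate partition coefficient
#'
#' `Kp` is the ratio of the mean intensity inside each segmented region to
#' the mean intensity of the dilute phase, computed once over all pixels
#' outside every labelled region. To limit point-spread bleed-through, a
#' dilation ring (default 2 px) around every region is excluded from the
#' dilute mean (set `exclude_ring_px = 0` to disable).
#'
#' @param img intensity image the segmentation was derived from.
#' @param seg a `segmentation_result` for `img`.
#' @param temperature_K temperature for the free-energy column, Kelvin.
#' @param exclude_ring_px width of the dilation ring excluded from the
#'   dilute mean, pixels.
#' @param r_as_printed if `TRUE`, use the literal constant 1.9872 for R
#'   (the value as printed in common partitioning pipelines, numerically
#'   the gas constant in cal/(mol K)); default uses 1.9872e-3 kcal/(mol K)
#'   so that `deltaG` is in kcal/mol.
#' @return data.frame with one row per region: `region_id`, `Kp`,
#'   `deltaG_kcal_mol`, `T_kelvin`, plus the shared `dilute_mean`.
#' @export
partition_coefficient <- function(img, seg, temperature_K = 298.15,
                                  exclude_ring_px = 2,
                                  r_as_printed = FALSE) {
  stop_if_not_matrix(img)
  if (!inherits(seg, "segmentation_result"))
    stop("`seg` must be a segmentation_result", call. = FALSE)
  if (!all(dim(seg$labels) == dim(img)))
    stop("segmentation geometry does not match image", call. = FALSE)
  labels <- seg$labels
  outside <- labels == 0
  if (exclude_ring_px > 0 && any(labels > 0)) {
    brush <- EBImage::makeBrush(2 * ceiling(exclude_ring_px) + 1,
                                shape = "disc")
    dil <- as_plain_matrix(EBImage::dilate(EBImage::Image((labels > 0) * 1), brush))
    outside <- dil == 0
  }
  if (!any(outside))
    stop("no dilute-phase pixels left outside regions", call. = FALSE)
  dilute_mean <- mean(img[outside])
  if (dilute_mean <= 0)
    stop("dilute-phase mean is not positive; correct the background offset upstream",
         call. = FALSE)
  regs <- seg$regions
  kp <- vapply(regs$region_id,
               function(id) mean(img[labels == id]) / dilute_mean,
               numeric(1))
  data.frame(region_id = regs$region_id,
             Kp = kp,
             deltaG_kcal_mol = delta_g(kp, temperature_K,
                                       r_as_printed = r_as_printed),
             T_kelvin = temperature_K,
             dilute_mean = dilute_mean)
}

#' Apparent transfer free energy from a partition coefficient
#'
#' `deltaG = -R * T * ln(Kp)`, the apparent free energy of transferring the
#' labelled species from the dilute to the dense phase. With the default
#' gas constant `R = 1.9872e-3` kcal/(mol K) the result is in kcal/mol;
#' `r_as_printed = TRUE` uses the literal 1.9872 instead, reproducing
#' pipelines that quote the constant in those units.
#'
#' @param Kp partition coefficient(s), > 0.
#' @param T_kelvin temperature, Kelvin.
#' @param r_as_printed use the literal printed constant (see Details).
#' @return free energy, kcal/mol (or cal/mol when `r_as_printed`).
#' @export
delta_g <- function(Kp, T_kelvin = 298.15, r_as_printed = FALSE) {
  if (any(!is.finite(Kp)) || any(Kp <= 0))
    stop("Kp must be positive and finite", call. = FALSE)
  if (T_kelvin <= 0) stop("temperature must be positive", call. = FALSE)
  R <- if (r_as_printed) R_PRINTED else R_KCAL
  -R * T_kelvin * log(Kp)
}

#' ROUT outlier removal for a single sample
#'
#' Robust outlier detection for values modelled as a constant plus noise:
#' the robust fit is the sample median, the scale is the robust standard
#' deviation of the residuals (68.27th percentile of their absolute values,
#' with a small-sample degrees-of-freedom correction), and outliers are
#' flagged by a false-discovery-rate test at rate `Q` on the two-sided
#' t-tail probabilities of the scaled residuals.
#'
#' @param values numeric vector, length >= 3.
#' @param Q false-discovery rate, percent (e.g. `1` = 1%). `Q = 0` removes
#'   nothing.
#' @return list with `kept`, `removed`, and `is_outlier` (logical aligned
#'   with the input).
#' @export
remove_outliers_rout <- function(values, Q = 1) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (Q < 0 || Q > 100) stop("Q must be in [0, 100] percent", call. = FALSE)
  n <- length(values)
  if (Q == 0 || length(unique(values)) == 1) {
    return(list(kept = values, removed = values[0],
                is_outlier = rep(FALSE, n)))
  }
  center <- median(values)
  res <- values - center
  df <- n - 1
  rsdr <- quantile(abs(res), 0.6827, names = FALSE) * n / df
  if (rsdr <= 0) {
    return(list(kept = values, removed = values[0],
                is_outlier = rep(FALSE, n)))
  }
  tval <- abs(res) / rsdr
  p <- 2 * pt(tval, df = df, lower.tail = FALSE)
  ord <- order(p)
  q <- Q / 100
  thresh <- q * seq_len(n) / n
  passing <- which(p[ord] <= thresh)
  is_out <- rep(FALSE, n)
  if (length(passing)) is_out[ord[seq_len(max(passing))]] <- TRUE
  list(kept = values[!is_out], removed = values[is_out], is_outlier = is_out)
}
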