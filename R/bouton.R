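# Super-resolution / expansion bouton quantification: marker-positive ROI
# extraction, actin enrichment, axial ring autocorrelation and cluster
# density.

#' Bouton ROIs from a vesicle-marker channel
#'
#' The marker channel is lightly smoothed (Gaussian, sigma 1 px) and
#' Otsu-thresholded into a mask; when a GFP channel is supplied (rescue
#' conditions) the ROI mask is the AND of both channels' masks, restricting
#' analysis to transfected cells. Connected components become ROIs with
#' area and circularity (`4 pi A / P^2`); optionally, low-circularity ROIs
#' (fused boutons) are re-split by watershed on the distance transform.
#'
#' @param marker_channel 2D marker image.
#' @param gfp_channel optional 2D image; when given, ROIs require both
#'   masks.
#' @param min_intensity optional named or 2-vector `(marker, gfp)` of
#'   minimum intensity thresholds added on top of Otsu (used for noisy
#'   expansion data).
#' @param split_by_circularity re-split ROIs with circularity below
#'   `circularity_threshold` by watershed.
#' @param circularity_threshold circularity below which an ROI is re-split.
#' @param min_area_px discard ROIs smaller than this.
#' @param smooth_sigma Gaussian sigma before thresholding, px.
#' @return list with `labels` (ROI label matrix) and `rois` (data.frame:
#'   `roi_id`, `y`, `x`, `area_px2`, `circularity`). Empty mask gives zero
#'   rows.
#' @export
bouton_rois <- function(marker_channel, gfp_channel = NULL,
                        min_intensity = NULL, split_by_circularity = FALSE,
                        circularity_threshold = 0.5, min_area_px = 5,
                        smooth_sigma = 1) {
  stop_if_not_matrix(marker_channel, "marker_channel")
  auto_mask <- function(img, floor_value) {
    sm <- if (smooth_sigma > 0)
      as_plain_matrix(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
    else img
    if (diff(range(sm)) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
    m <- sm > otsu_threshold(sm)
    if (!is.null(floor_value)) m <- m & (img > floor_value)
    m
  }
  thr_marker <- if (!is.null(min_intensity)) min_intensity[[1]] else NULL
  mask <- auto_mask(marker_channel, thr_marker)
  if (!is.null(gfp_channel)) {
    if (!all(dim(gfp_channel) == dim(marker_channel)))
      stop("channel shapes differ", call. = FALSE)
    thr_gfp <- if (!is.null(min_intensity) && length(min_intensity) > 1)
      min_intensity[[2]] else NULL
    mask <- mask & auto_mask(gfp_channel, thr_gfp)
  }
  empty <- list(labels = matrix(0L, nrow(marker_channel), ncol(marker_channel)),
                rois = data.frame(roi_id = integer(0), y = numeric(0),
                                  x = numeric(0), area_px2 = numeric(0),
                                  circularity = numeric(0)))
  if (!any(mask)) return(empty)
  labels <- label_components(mask)
  roi_table <- function(labels) {
    props <- region_props(labels)
    shp <- EBImage::computeFeatures.shape(labels)
    circ <- 4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2
    data.frame(roi_id = props$region_id, y = props$y, x = props$x,
               area_px2 = props$area_px2,
               circularity = pmin(as.numeric(circ), 1))
  }
  tab <- roi_table(labels)
  if (split_by_circularity && any(tab$circularity < circularity_threshold)) {
    bad <- tab$roi_id[tab$circularity < circularity_threshold]
    submask <- matrix(labels %in% bad, nrow(labels), ncol(labels))
    dm <- EBImage::distmap(EBImage::Image(submask * 1))
    w <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    w <- matrix(as.integer(w), nrow(labels), ncol(labels))
    labels[submask] <- 0L
    labels[w > 0] <- max(tab$roi_id) + w[w > 0]
    labels[labels > 0] <- match(labels[labels > 0],
                                sort(unique(labels[labels > 0])))
    tab <- roi_table(labels)
  }
  keep <- tab$area_px2 >= min_area_px
  if (!all(keep)) {
    labels[!(labels %in% tab$roi_id[keep])] <- 0L
    labels[labels > 0] <- match(labels[labels > 0],
                                sort(tab$roi_id[keep]))
    tab <- roi_table(labels)
  }
  rownames(tab) <- NULL
  list(labels = labels, rois = tab)
}

#' Normalized actin enrichment per bouton ROI
#'
#' For each ROI, the maximum actin intensity divided by the maximum of the
#' whole actin image; summarized as the per-image median, the quantity
#' compared across conditions. The normalization makes the measure
#' invariant to multiplicative intensity rescaling.
#'
#' @param rois output of [bouton_rois()] (or a bare label matrix).
#' @param actin_channel 2D actin image.
#' @return list with `per_roi` (data.frame `roi_id`, `max_actin_raw`,
#'   `max_actin_norm`) and `image_median` (median of `max_actin_norm`).
#' @export
actin_enrichment <- function(rois, actin_channel) {
  stop_if_not_matrix(actin_channel, "actin_channel")
  labels <- if (is.list(rois)) rois$labels else rois
  if (!all(dim(labels) == dim(actin_channel)))
    stop("ROI labels and actin channel shapes differ", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) stop("no ROIs to measure", call. = FALSE)
  gmax <- max(actin_channel)
  if (gmax <= 0)
    stop("actin channel maximum is not positive; normalization undefined",
         call. = FALSE)
  mx <- vapply(ids, function(id) max(actin_channel[labels == id]),
               numeric(1))
  per_roi <- data.frame(roi_id = ids, max_actin_raw = mx,
                        max_actin_norm = mx / gmax)
  list(per_roi = per_roi, image_median = median(per_roi$max_actin_norm),
       image_max = gmax)
}

#' Autocorrelation of an axial intensity profile and its dominant period
#'
#' Mean-subtracted, variance-normalized autocorrelation over lags; the
#' dominant period is the lag of the first local maximum after the zero-lag
#' peak. A period is reported as significant only when that maximum
#' exceeds a white-noise 95% confidence band corrected for the number of
#' lags examined (Bonferroni on the per-lag `1/sqrt(n)` null sd), so a
#' featureless profile rarely yields a spurious period.
#'
#' @param profile numeric intensity profile (length at least 3x the
#'   expected period in pixels for a stable estimate).
#' @param pixel_um sampling step, micrometers.
#' @param max_lag_um largest lag examined; defaults to half the profile.
#' @return list with `lag_um`, `acf` (normalized, `acf[1] = 1` at lag 0),
#'   `period_um` (NA when no local maximum exists), `significant`.
#' @export
ring_autocorrelation <- function(profile, pixel_um, max_lag_um = NULL) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 8) stop("profile too short", call. = FALSE)
  if (var(profile) == 0)
    stop("constant profile: autocorrelation undefined", call. = FALSE)
  max_lag <- if (is.null(max_lag_um)) floor(n / 2)
             else min(n - 1, round(max_lag_um / pixel_um))
  a <- as.numeric(acf(profile, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf)
  lags <- (seq_along(a) - 1) * pixel_um
  # first local maximum after lag 0
  per <- NA_real_; peak <- NA_real_
  if (length(a) >= 3) {
    interior <- 2:(length(a) - 1)
    locmax <- interior[a[interior] > a[interior - 1] &
                       a[interior] >= a[interior + 1]]
    if (length(locmax)) {
      per <- lags[locmax[1]]
      peak <- a[locmax[1]]
    }
  }
  m <- length(a) - 1L
  band <- qnorm(1 - 0.025 / max(m, 1)) / sqrt(n)
  list(lag_um = lags, acf = a, period_um = per,
       significant = is.finite(peak) && peak > band, conf_band = band)
}

#' Cluster density inside an axon mask
#'
#' Connected components of `img > theta_intensity` restricted to the axon
#' mask, kept when their area exceeds `theta_area_px`, and counted per
#' mask area. Defaults mirror a raw-count pipeline (4000 counts, 10 px).
#'
#' @param img 2D intensity image (raw counts).
#' @param axon_mask binary mask of the axon surface; must be nonempty.
#' @param theta_intensity intensity threshold (strict `>`).
#' @param theta_area_px area threshold in pixels (strict `>`).
#' @param pixel_size_um when given, the density is per um^2 instead of per
#'   px^2.
#' @return list (class `density_result`) with `n_objects`, `axon_area`
#'   (px^2 or um^2), `density`, `labels`.
#' @export
cluster_density <- function(img, axon_mask, theta_intensity = 4000,
                            theta_area_px = 10, pixel_size_um = NULL) {
  stop_if_not_matrix(img)
  axon_mask <- as_binary(axon_mask)
  if (!any(axon_mask)) stop("axon mask is empty", call. = FALSE)
  if (!all(dim(axon_mask) == dim(img)))
    stop("mask and image shapes differ", call. = FALSE)
  cand <- (img > theta_intensity) & axon_mask
  labels <- label_components(cand)
  sizes <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  keep <- which(sizes > theta_area_px)
  labels[!(labels %in% keep)] <- 0L
  if (length(keep)) labels[labels > 0] <- match(labels[labels > 0], sort(keep))
  area <- sum(axon_mask)
  scale <- 1
  if (!is.null(pixel_size_um)) {
    area <- area * pixel_size_um^2
    scale <- pixel_size_um^2
  }
  structure(list(n_objects = length(keep), axon_area = area,
                 density = length(keep) / area, labels = labels,
                 theta_intensity = theta_intensity,
                 theta_area_px = theta_area_px),
            class = "density_result")
}

#' @exportS3Method
print.density_result <- function(x, ...) {
  cat("<density_result>", x$n_objects, "objects over", x$axon_area,
      "area units; density", signif(x$density, 4), "\n")
  invisible(x)
}
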