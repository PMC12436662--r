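# Ground-truthed synthetic scenes. Every generator is deterministic in
# (params, seed) and records the planted truth so the matching analysis
# operation can be validated without external data.

new_synth_scene <- function(image, truth, seed, params) {
  structure(list(image = image, truth = truth, seed = as.integer(seed),
                 params = params),
            class = "synth_scene")
}

#' @exportS3Method
print.synth_scene <- function(x, ...) {
  d <- if (is.matrix(x$image)) dim(x$image) else dim(x$image)
  cat("<synth_scene>", paste(d, collapse = "x"),
      " seed:", x$seed, "\n")
  cat("  truth fields:", paste(names(x$truth), collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic field of bright condensates in a dim dilute phase
#'
#' Plants `n` non-overlapping disks (flat profile convolved with a Gaussian
#' point-spread function) on a uniform dilute background. The dense-phase
#' amplitude is solved so that the ratio of mean intensity inside the planted
#' disks to the mean intensity outside equals `kp_true` exactly before noise,
#' which makes the scene a construction oracle for
#' [partition_coefficient()].
#'
#' @param n number of condensates (>= 0).
#' @param radius_px disk radius in pixels (>= 1).
#' @param kp_true target partition coefficient (> 0), the planted ratio of
#'   dense to dilute mean intensity.
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   intensity units (the dilute level defaults to 100, so e.g.
#'   `noise_sd = 0.02 * 100` is 2% of the dilute level).
#' @param seed integer RNG seed; identical `(params, seed)` reproduce the
#'   scene bit-for-bit.
#' @param dim image size `c(ny, nx)`.
#' @param dilute_intensity dilute-phase level, arbitrary units.
#' @param psf_sigma Gaussian PSF sigma in pixels.
#' @param pixel_size_um physical pixel size, micrometers.
#' @return A `synth_scene` whose `truth` holds `condensate_centers` (matrix
#'   of (y, x)), `condensate_radii`, `dense_intensity`, `dilute_intensity`.
#' @export
make_condensate_field <- function(n, radius_px = 12, kp_true = 4,
                                  noise_sd = 0, seed = 1L,
                                  dim = c(192L, 192L),
                                  dilute_intensity = 100,
                                  psf_sigma = 1, pixel_size_um = 0.1) {
  stopifnot(n >= 0, radius_px >= 1, kp_true > 0, noise_sd >= 0,
            dilute_intensity > 0)
  ny <- dim[1]; nx <- dim[2]
  if (n * pi * radius_px^2 > 0.3 * ny * nx)
    stop("capacity exceeded: requested disks cover more than 30% of the frame",
         call. = FALSE)
  params <- list(n = n, radius_px = radius_px, kp_true = kp_true,
                 noise_sd = noise_sd, dim = c(ny, nx),
                 dilute_intensity = dilute_intensity, psf_sigma = psf_sigma,
                 pixel_size_um = pixel_size_um)
  with_local_seed(seed, {
    margin <- radius_px + ceiling(4 * psf_sigma) + 1
    centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x")))
    tries <- 0L
    while (nrow(centers) < n) {
      if (tries > 200L * max(n, 1L))
        stop("placement failed: could not place non-overlapping disks",
             call. = FALSE)
      tries <- tries + 1L
      cand <- c(runif(1, margin, ny - margin), runif(1, margin, nx - margin))
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cand[1])^2 +
                   (centers[, 2] - cand[2])^2) > 2 * radius_px + 3)) {
        centers <- rbind(centers, cand)
      }
    }
    indicator <- matrix(0, ny, nx)
    for (i in seq_len(nrow(centers)))
      indicator <- indicator | raster_disk(ny, nx, centers[i, 1],
                                           centers[i, 2], radius_px)
    indicator <- indicator * 1
    if (n > 0) {
      blurred <- as_plain_matrix(EBImage::gblur(EBImage::Image(indicator),
                                          sigma = psf_sigma))
      inside <- indicator > 0
      m_in <- mean(blurred[inside]); m_out <- mean(blurred[!inside])
      # solve (dilute + a*m_in) / (dilute + a*m_out) == kp_true
      amp <- dilute_intensity * (kp_true - 1) / (m_in - kp_true * m_out)
      if (!is.finite(amp) || amp <= 0)
        stop("kp_true not representable with this PSF/geometry", call. = FALSE)
      img <- dilute_intensity + amp * blurred
      dense <- dilute_intensity + amp * m_in
    } else {
      img <- matrix(dilute_intensity, ny, nx)
      dense <- dilute_intensity
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
    truth <- list(condensate_centers = centers,
                  condensate_radii = rep(radius_px, nrow(centers)),
                  dense_intensity = dense,
                  dilute_intensity = dilute_intensity,
                  kp_true = kp_true,
                  pixel_size_um = pixel_size_um)
    new_synth_scene(img, truth, seed, params)
  })
}

#' Synthetic actin aster scene
#'
#' Places condensates (disks) with `filaments_per` straight bright filaments
#' radiating from each center at random angles, rendered with a Gaussian
#' cross-section, on channel 2 ("actin"); channel 1 ("synapsin") holds the
#' condensate disks alone. Optionally a bridging filament connects the first
#' two condensate centers, emulating inter-condensate actin fibers.
#'
#' @param n_condensates number of condensates.
#' @param filaments_per straight filaments radiating per condensate (>= 0).
#' @param filament_len_px filament length in pixels, measured from the
#'   condensate center.
#' @param seed integer RNG seed.
#' @param dim image size `c(ny, nx)`.
#' @param condensate_radius_px condensate disk radius.
#' @param filament_sigma_px Gaussian cross-section sigma of rendered
#'   filaments (2-px apparent width at the default 0.8).
#' @param bridge add a filament joining condensates 1 and 2.
#' @param noise_sd additive Gaussian noise sd (intensity units; signal
#'   amplitude is 1).
#' @param pixel_size_um physical pixel size, micrometers.
#' @return `synth_scene` with `image` an array `[y, x, channel]`
#'   (channels `"synapsin"`, `"actin"`) and truth fields
#'   `condensate_centers`, `condensate_radii`, `filament_segments` (list of
#'   2x2 matrices, rows = endpoints (y, x)), `filaments_per`.
#' @export
make_aster_scene <- function(n_condensates = 1, filaments_per = 6,
                             filament_len_px = 40, seed = 1L,
                             dim = c(128L, 128L), condensate_radius_px = 5,
                             filament_sigma_px = 0.8, bridge = FALSE,
                             noise_sd = 0, pixel_size_um = 0.1) {
  stopifnot(n_condensates >= 1, filaments_per >= 0, filament_len_px >= 1)
  ny <- dim[1]; nx <- dim[2]
  margin <- condensate_radius_px + filament_len_px + 3
  if (2 * margin >= min(ny, nx))
    stop("frame too small for requested filament length", call. = FALSE)
  params <- as.list(environment())[c("n_condensates", "filaments_per",
                                     "filament_len_px", "dim",
                                     "condensate_radius_px",
                                     "filament_sigma_px", "bridge",
                                     "noise_sd", "pixel_size_um")]
  with_local_seed(seed, {
    centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x")))
    tries <- 0L
    while (nrow(centers) < n_condensates) {
      if (tries > 500L * n_condensates)
        stop("placement failed for condensates", call. = FALSE)
      tries <- tries + 1L
      cand <- c(runif(1, margin, ny - margin), runif(1, margin, nx - margin))
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
              2 * condensate_radius_px + 6))
        centers <- rbind(centers, cand)
    }
    syn <- matrix(0, ny, nx)
    act <- matrix(0, ny, nx)
    segments <- list()
    angles <- matrix(NA_real_, n_condensates, max(filaments_per, 1))
    for (i in seq_len(n_condensates)) {
      syn[raster_disk(ny, nx, centers[i, 1], centers[i, 2],
                      condensate_radius_px)] <- 1
      act[raster_disk(ny, nx, centers[i, 1], centers[i, 2],
                      condensate_radius_px)] <- 0.8
      if (filaments_per > 0) {
        # jittered equal spacing keeps rays well separated at the hub
        base <- runif(1, 0, 2 * pi)
        th <- base + (seq_len(filaments_per) - 1) * 2 * pi / filaments_per +
          runif(filaments_per, -0.12, 0.12) * 2 * pi / max(filaments_per, 4)
        angles[i, seq_len(filaments_per)] <- th
        for (j in seq_len(filaments_per)) {
          y1 <- centers[i, 1] + filament_len_px * sin(th[j])
          x1 <- centers[i, 2] + filament_len_px * cos(th[j])
          act <- add_gaussian_segment(act, centers[i, 1], centers[i, 2],
                                      y1, x1, sigma = filament_sigma_px,
                                      amplitude = 1)
          segments[[length(segments) + 1L]] <-
            matrix(c(centers[i, 1], centers[i, 2], y1, x1), 2, 2,
                   byrow = TRUE, dimnames = list(NULL, c("y", "x")))
        }
      }
    }
    if (bridge && n_condensates >= 2) {
      act <- add_gaussian_segment(act, centers[1, 1], centers[1, 2],
                                  centers[2, 1], centers[2, 2],
                                  sigma = filament_sigma_px, amplitude = 1)
      segments[[length(segments) + 1L]] <-
        matrix(c(centers[1, ], centers[2, ]), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("y", "x")))
    }
    if (noise_sd > 0) {
      act <- act + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
      syn <- syn + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
    }
    img <- array(c(syn, act), dim = c(ny, nx, 2),
                 dimnames = list(NULL, NULL, c("synapsin", "actin")))
    truth <- list(condensate_centers = centers,
                  condensate_radii = rep(condensate_radius_px, n_condensates),
                  filament_segments = segments,
                  filaments_per = filaments_per,
                  filament_len_px = filament_len_px,
                  bridge = bridge,
                  dense_intensity = 1, dilute_intensity = 1e-6,
                  pixel_size_um = pixel_size_um)
    new_synth_scene(img, truth, seed, params)
  })
}

#' Synthetic axial actin-ring line profile
#'
#' A sinusoid of known spatial period on a constant baseline, emulating the
#' periodic membrane-associated actin rings seen along axons in STED imaging
#' (period about 190 nm at 20 nm pixels).
#'
#' @param period_um ring period, micrometers; must exceed `2 * pixel_um`
#'   (Nyquist).
#' @param pixel_um sampling step, micrometers.
#' @param length_um profile length, micrometers.
#' @param noise_sd additive Gaussian noise sd (signal amplitude is
#'   `amplitude`).
#' @param seed integer RNG seed.
#' @param baseline,amplitude sinusoid baseline and amplitude.
#' @return list with `profile` (numeric), `position_um`, and `truth`
#'   (`ring_period_um`, `n_cycles`, `baseline`, `amplitude`).
#' @export
make_ring_profile <- function(period_um = 0.19, pixel_um = 0.02,
                              length_um = 10, noise_sd = 0, seed = 1L,
                              baseline = 1, amplitude = 0.5) {
  if (period_um <= 2 * pixel_um)
    stop("Nyquist violation: period_um must exceed 2 * pixel_um",
         call. = FALSE)
  n <- round(length_um / pixel_um)
  pos <- (seq_len(n) - 1) * pixel_um
  with_local_seed(seed, {
    prof <- baseline + amplitude * cos(2 * pi * pos / period_um)
    if (noise_sd > 0) prof <- prof + rnorm(n, sd = noise_sd)
    list(profile = prof, position_um = pos,
         truth = list(ring_period_um = period_um,
                      n_cycles = length_um / period_um,
                      baseline = baseline, amplitude = amplitude,
                      pixel_um = pixel_um))
  })
}

#' Gompertz law of normalized enrichment
#'
#' `Y(X) = YM * (Y0 / YM) ^ exp(-K * X)`: sigmoidal growth from initial
#' value `Y0` at `X = 0` to plateau `YM`, with rate constant `K` (per
#' minute when `X` is minutes).
#'
#' @param x time points.
#' @param YM plateau value.
#' @param Y0 initial value (`0 < Y0 < YM`).
#' @param K rate constant.
#' @return model values at `x`.
#' @export
gompertz <- function(x, YM, Y0, K) {
  YM * (Y0 / YM)^(exp(-K * x))
}

#' Synthetic actin-enrichment movie with rigid drift
#'
#' A single condensate whose actin-channel amplitude follows the Gompertz
#' law while the object translates by `drift_px_per_frame` each frame,
#' emulating stage drift during time-lapse acquisition.
#'
#' @param gompertz_params named vector `c(YM=, Y0=, K=)`.
#' @param n_frames number of frames (>= 3).
#' @param dt_min frame interval, minutes.
#' @param drift_px_per_frame numeric `(dy, dx)` translation per frame,
#'   pixels (may be fractional).
#' @param noise_sd additive Gaussian noise sd (intensity units; enrichment
#'   amplitude is `amp`).
#' @param seed integer RNG seed.
#' @param dim frame size `c(ny, nx)`.
#' @param radius_px condensate radius.
#' @param background background (dilute) level.
#' @param amp intensity amplitude multiplying the Gompertz value.
#' @param psf_sigma Gaussian PSF sigma, pixels.
#' @return `synth_scene` with `image` an array `[y, x, t]` and truth fields
#'   `gompertz_params`, `times_min`, `drift_per_frame`, `center`,
#'   `radius_px`.
#' @export
make_enrichment_movie <- function(gompertz_params = c(YM = 0.9611,
                                                      Y0 = 0.01032,
                                                      K = 0.2958),
                                  n_frames = 36, dt_min = 1,
                                  drift_px_per_frame = c(0, 0),
                                  noise_sd = 0, seed = 1L,
                                  dim = c(64L, 64L), radius_px = 10,
                                  background = 0.05, amp = 1,
                                  psf_sigma = 1) {
  stopifnot(n_frames >= 3)
  YM <- gompertz_params[["YM"]]; Y0 <- gompertz_params[["Y0"]]
  K <- gompertz_params[["K"]]
  if (!(Y0 > 0 && Y0 < YM)) stop("need 0 < Y0 < YM", call. = FALSE)
  ny <- dim[1]; nx <- dim[2]
  c0 <- c(ny / 2, nx / 2)
  cend <- c0 + (n_frames - 1) * drift_px_per_frame
  lim <- radius_px + ceiling(4 * psf_sigma) + 1
  if (any(c(c0, cend) < lim) || cend[1] > ny - lim || cend[2] > nx - lim ||
      c0[1] > ny - lim || c0[2] > nx - lim)
    stop("drift carries the condensate out of frame", call. = FALSE)
  times <- (seq_len(n_frames) - 1) * dt_min
  yvals <- gompertz(times, YM, Y0, K)
  params <- list(gompertz_params = gompertz_params, n_frames = n_frames,
                 dt_min = dt_min, drift_px_per_frame = drift_px_per_frame,
                 noise_sd = noise_sd, dim = c(ny, nx), radius_px = radius_px,
                 background = background, amp = amp, psf_sigma = psf_sigma)
  with_local_seed(seed, {
    mov <- array(0, dim = c(ny, nx, n_frames))
    for (f in seq_len(n_frames)) {
      cf <- c0 + (f - 1) * drift_px_per_frame
      disk <- raster_disk(ny, nx, cf[1], cf[2], radius_px) * 1
      blur <- as_plain_matrix(EBImage::gblur(EBImage::Image(disk),
                                       sigma = psf_sigma))
      fr <- background + amp * yvals[f] * blur
      if (noise_sd > 0) fr <- fr + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
      mov[, , f] <- fr
    }
    truth <- list(gompertz_params = c(YM = YM, Y0 = Y0, K = K),
                  times_min = times, drift_per_frame = drift_px_per_frame,
                  center = c0, radius_px = radius_px,
                  dense_intensity = background + amp,
                  dilute_intensity = background,
                  values = yvals)
    new_synth_scene(mov, truth, seed, params)
  })
}

#' Synthetic two-channel bouton scene
#'
#' Channel 1 carries vesicle-marker puncta (Gaussian spots); channel 2
#' carries an actin channel in which a known subset of the puncta is
#' enriched, emulating two-color super-resolution bouton images.
#'
#' @param n_puncta number of marker puncta.
#' @param enriched_fraction fraction of puncta carrying elevated actin
#'   (0..1); the enriched subset is recorded in the truth.
#' @param seed integer RNG seed.
#' @param dim image size.
#' @param punctum_radius_px marker punctum Gaussian sigma, pixels.
#' @param actin_background actin dilute level.
#' @param actin_amp actin amplitude inside enriched puncta.
#' @param noise_sd additive Gaussian noise sd.
#' @return `synth_scene`; `image` is `[y, x, channel]` with channels
#'   `"marker"`, `"actin"`; truth holds `punctum_centers`, `enriched`
#'   (logical per punctum), levels.
#' @export
make_bouton_scene <- function(n_puncta = 20, enriched_fraction = 0.5,
                              seed = 1L, dim = c(256L, 256L),
                              punctum_radius_px = 4,
                              actin_background = 0.1, actin_amp = 1,
                              noise_sd = 0) {
  stopifnot(enriched_fraction >= 0, enriched_fraction <= 1, n_puncta >= 0)
  ny <- dim[1]; nx <- dim[2]
  params <- list(n_puncta = n_puncta, enriched_fraction = enriched_fraction,
                 dim = c(ny, nx), punctum_radius_px = punctum_radius_px,
                 actin_background = actin_background, actin_amp = actin_amp,
                 noise_sd = noise_sd)
  with_local_seed(seed, {
    margin <- 6 * punctum_radius_px
    centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x")))
    tries <- 0L
    while (nrow(centers) < n_puncta) {
      if (tries > 500L * max(n_puncta, 1L))
        stop("placement failed for puncta", call. = FALSE)
      tries <- tries + 1L
      cand <- c(runif(1, margin, ny - margin), runif(1, margin, nx - margin))
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
              6 * punctum_radius_px))
        centers <- rbind(centers, cand)
    }
    n_enriched <- round(enriched_fraction * n_puncta)
    enriched <- rep(FALSE, n_puncta)
    if (n_enriched > 0) enriched[sample.int(n_puncta, n_enriched)] <- TRUE
    marker <- matrix(0, ny, nx)
    actin <- matrix(actin_background, ny, nx)
    for (i in seq_len(n_puncta)) {
      marker <- add_gaussian_segment(marker, centers[i, 1], centers[i, 2],
                                     centers[i, 1], centers[i, 2],
                                     sigma = punctum_radius_px, amplitude = 1)
      if (enriched[i])
        actin <- add_gaussian_segment(actin, centers[i, 1], centers[i, 2],
                                      centers[i, 1], centers[i, 2],
                                      sigma = punctum_radius_px,
                                      amplitude = actin_amp)
    }
    if (noise_sd > 0) {
      marker <- marker + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
      actin <- actin + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
    }
    img <- array(c(marker, actin), dim = c(ny, nx, 2),
                 dimnames = list(NULL, NULL, c("marker", "actin")))
    truth <- list(punctum_centers = centers, enriched = enriched,
                  dense_intensity = actin_background + actin_amp,
                  dilute_intensity = actin_background)
    new_synth_scene(img, truth, seed, params)
  })
}

#' Synthetic phalloidin-cluster scene for density analysis
#'
#' Plants clusters inside an axon mask with controlled peak intensity and
#' area so that exactly a known subset passes an (intensity, area) double
#' threshold, providing the ground truth for [cluster_density()].
#'
#' @param n_above clusters exceeding both thresholds.
#' @param n_dim clusters below the intensity threshold (but large enough).
#' @param n_small clusters above the intensity threshold but at or below
#'   the area threshold.
#' @param theta_intensity,theta_area_px the thresholds the scene is built
#'   around (defaults match a raw-count pipeline: 4000 counts, 10 px).
#' @param seed integer RNG seed.
#' @param dim image size.
#' @param background background level, counts.
#' @return `synth_scene` with `image` in raw counts, truth holding the
#'   `axon_mask`, per-cluster centers and the expected passing count
#'   `n_pass`.
#' @export
make_cluster_scene <- function(n_above = 3, n_dim = 1, n_small = 1,
                               theta_intensity = 4000, theta_area_px = 10,
                               seed = 1L, dim = c(192L, 192L),
                               background = 500) {
  ny <- dim[1]; nx <- dim[2]
  params <- list(n_above = n_above, n_dim = n_dim, n_small = n_small,
                 theta_intensity = theta_intensity,
                 theta_area_px = theta_area_px, dim = c(ny, nx),
                 background = background)
  with_local_seed(seed, {
    axon <- matrix(FALSE, ny, nx)
    axon[, round(nx * 0.2):round(nx * 0.8)] <- TRUE   # axon as a wide band
    ntot <- n_above + n_dim + n_small
    margin <- 12
    xlo <- round(nx * 0.2) + margin; xhi <- round(nx * 0.8) - margin
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < ntot) {
      if (tries > 500L * max(ntot, 1L))
        stop("placement failed for clusters", call. = FALSE)
      tries <- tries + 1L
      cand <- c(runif(1, margin, ny - margin), runif(1, xlo, xhi))
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
              16))
        centers <- rbind(centers, cand)
    }
    kind <- rep(c("above", "dim", "small"), c(n_above, n_dim, n_small))
    img <- matrix(background, ny, nx)
    for (i in seq_len(ntot)) {
      if (kind[i] == "above") {        # bright and big: passes both
        lev <- theta_intensity * 2
        disk <- raster_disk(ny, nx, centers[i, 1], centers[i, 2], 3.5)
      } else if (kind[i] == "dim") {   # big but below intensity cut
        lev <- theta_intensity * 0.5
        disk <- raster_disk(ny, nx, centers[i, 1], centers[i, 2], 3.5)
      } else {                         # bright but too small (<= area cut)
        lev <- theta_intensity * 2
        disk <- raster_disk(ny, nx, centers[i, 1], centers[i, 2], 1.6)
        if (sum(disk) > theta_area_px)  # keep it at or under the area cut
          disk <- raster_disk(ny, nx, centers[i, 1], centers[i, 2], 1.2)
      }
      img[disk] <- lev
    }
    truth <- list(cluster_centers = centers, kind = kind,
                  axon_mask = axon, n_pass = n_above,
                  dense_intensity = theta_intensity * 2,
                  dilute_intensity = background)
    new_synth_scene(img, truth, seed, params)
  })
}
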