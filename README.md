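# condactin

Quantification pipelines for fluorescence images of biomolecular
condensates and the actin networks they nucleate.

Synapsin-1 condensates — with or without synaptic vesicles — sequester
G-actin and trigger its polymerization into radial "asters", rim "toruses"
and inter-condensate fibers. Quantifying that biology from microscopy data
takes a family of small, bespoke pipelines: condensate segmentation with
partition-coefficient thermodynamics, filament network reconstruction and
Sholl profiling, node morphometrics with clustering and PCA, Gompertz
enrichment kinetics, and super-resolution bouton/ring/density
quantification with the accompanying statistics. `condactin` implements
all of them as tested, reusable R functions, together with a
synthetic-scene generator that plants known ground truth so every pipeline
can be validated without external data.

## The quantities at the core

* **Partitioning.** Per condensate, `Kp = mean(inside) / mean(outside)`
  (dilute mean computed globally outside all condensates) and the apparent
  transfer free energy `ΔG = −RT·ln(Kp)` with
  `R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹`, `T = 298.15 K` by default.
* **Network reconstruction.** Difference-of-Gaussians enhancement (σ = 1
  minus σ = 2 px), iterative median despeckling (2 passes, radius 2 px),
  connection-restoring OR with the thresholded original, Zhang–Suen
  skeletonization, and graph tracing with segments < 3 px discarded.
* **Sholl profile.** Crossing counts of traced filaments with concentric
  circles in 0.5 µm increments around condensate centers, compared across
  conditions with `intersections ~ condition × radius + (1 | condensate)`
  (permutation fallback for singular fits).
* **Node morphometrics.** Watershed splitting on the distance transform,
  ten properties per node (volume, surface, diameter, three axis lengths,
  mean/max/min intensity, median Euclidean distance to other nodes),
  Pearson co-dependency matrix, k-means with silhouette-chosen k, PCA.
* **Kinetics.** Rigid drift registration, ROI time series, and the
  Gompertz law `Y(X) = YM·(Y0/YM)^exp(−K·X)` fitted by
  Levenberg–Marquardt.
* **Bouton / ring / density.** Normalized per-ROI maximum actin intensity
  in marker-positive boutons, axial ring autocorrelation with dominant
  period, cluster density above an (intensity > 4000, area > 10 px)
  double threshold, and the Grubbs/ROUT + Shapiro-gated
  Mann–Whitney/Welch two-group comparison.

## Worked example

Segment a synthetic condensate field with a planted partition coefficient
of 4 and recover it:

```r
library(condactin)
scene <- make_condensate_field(n = 6, kp_true = 4, noise_sd = 2, seed = 104)
seg   <- segment_condensates(scene$image, gaussian_sigma_px = 2)
pk    <- partition_coefficient(scene$image, seg)
mean(pk$Kp)
#> [1] 4.025592
mean(pk$deltaG_kcal_mol)
#> [1] -0.825135
```

The measured `Kp` is within 1% of the planted ratio; the corresponding
transfer free energy of −0.83 kcal/mol says partitioning into the dense
phase is favorable. Fit enrichment kinetics on a drifting movie:

```r
mv  <- make_enrichment_movie(c(YM = 0.9611, Y0 = 0.01032, K = 0.2958),
                             n_frames = 36, drift_px_per_frame = c(0.5, 0),
                             noise_sd = 0.01, seed = 13, dim = c(96L, 64L))
reg <- register_translation(mv$image)
roi <- with(mv$truth, (row(matrix(0, 96, 64)) - center[1])^2 +
                      (col(matrix(0, 96, 64)) - center[2])^2 <= radius_px^2)
fit <- fit_gompertz(roi_timeseries(reg$corrected, roi))
fit
#> <gompertz_fit> YM = 0.9948, Y0 = 0.01045, K = 0.2964 (1/K = 3.374), R2 = 0.9999
```

The rate constant is recovered to 0.2% despite 17.5 px of cumulative
drift; `1/K ≈ 3.4 min` is the characteristic enrichment time.

The numbered scripts under `analysis/` run the full set of analyses over
simulated scenes (01 simulation, 02 partitioning, 03 network + Sholl,
04 morphometrics, 05 kinetics, 06 bouton/ring/density) and write their
tables under `results/`.

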