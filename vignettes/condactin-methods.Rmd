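---
title: "Quantifying condensate-nucleated actin networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensate-nucleated actin networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condactin)
```

`condactin` quantifies fluorescence images of biomolecular condensates
(synapsin-1, with or without synaptic vesicles) and the actin networks they
nucleate. This vignette explains the underlying models, the tunable
parameters, the synthetic-data generators that ground-truth every pipeline,
and the numerical choices made where the methods literature leaves the
design open.

## Conventions

All images are plain numeric matrices indexed `[y, x]` with the row
coordinate increasing downward. Coordinates reported in tables are
**1-based pixel centers**, the natural R convention (a 0-based convention
would invite off-by-one errors in a language whose arrays start at 1).
Physical units enter only through `pixel_size_um`; every exported column
carries a unit suffix (`_um`, `_px`, `_kcal_mol`). Connectivity is
8-connected throughout.

## Partitioning thermodynamics

Condensates are segmented by Otsu thresholding after Gaussian smoothing
(`gaussian_sigma_px`, default 2 px — the smoothing scale matters more than
its exact value because the dense/dilute contrast is large). For each
region the partition coefficient is

$$K_p = \frac{\text{mean intensity inside the condensate}}
             {\text{mean intensity outside}}$$

with the dilute mean computed **once, globally**, over all pixels outside
every labelled region. Whether the dilute reference should be global or
local per condensate is genuinely open; the global reading matches the
verbal definition of the ratio and makes all regions in an image share one
denominator, which the two-region unit test pins down. A 2-px dilation
ring around each region is excluded from the dilute mean to avoid
point-spread bleed-through (`exclude_ring_px = 0` disables this).

The apparent transfer free energy is $\Delta G = -RT\ln K_p$. The
constant 1.9872 often quoted with this formula is numerically the gas
constant in cal mol⁻¹ K⁻¹; using it verbatim while labelling the result
kcal/mol overstates magnitudes a thousand-fold. `delta_g()` therefore uses
$R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹ by default and offers
`r_as_printed = TRUE` to reproduce pipelines that use the literal value.
Temperature defaults to 298.15 K. `Kp = 1` maps to $\Delta G = 0$, and
$\Delta G(1/K_p) = -\Delta G(K_p)$ exactly.

Outlier removal for `Kp` samples uses a ROUT-style procedure: a robust fit
of the constant model (sample median), a robust residual scale (the
68.27th percentile of absolute residuals with an $n/(n-1)$ correction),
and a false-discovery-rate cut at rate `Q` (percent) on the two-sided
t-tail probabilities of the scaled residuals. `Q = 0` removes nothing.

## Network reconstruction

The actin channel is band-pass filtered by a difference of Gaussians
(sigma 1.0 minus sigma 2.0 px — narrow minus wide, so thin fibrils respond
positively), thresholded (Otsu), despeckled by an iterative median filter
(two passes, circular element of radius 2 px), and then OR-ed with the
Otsu-thresholded original image. Running the connection-restoring OR
**after** the median filter is a deliberate ordering: the radius-2 median
erodes structures only ~2 px wide, and fibrils recovered from the original
threshold would otherwise be re-eroded; applying the restore step last
preserves both the despeckling of the background and the thin
fibril–condensate connections it exists to protect.

The mask is thinned to a 1-px skeleton (Zhang–Suen) and traced into a
graph: junction pixels (degree ≥ 3 in the redundancy-pruned pixel
adjacency) and endpoints become nodes, adjacent junction pixels merge into
a single node, and the pixel paths between nodes become edges with
Euclidean step lengths (1 or √2 px). Every traced segment shorter than
`min_segment_px` (default 3 px) is discarded and the graph re-simplified,
iterating to a fixed point; pruning can therefore dissolve tiny hub
artifacts as well as terminal spurs. Thinning has medial-axis semantics: a
bar of width $w$ loses about $w/2$ at each cap, so a 50×4 px bar traces to
roughly 46 px — the tests encode this rather than pretending the full
rectangle length is recoverable. Tracing is fully automatic; no
interactive editing step is modelled, which makes the whole chain
deterministic and testable.

## Sholl profiling

Intersection counts use concentric **circles** in the image plane, not
spheres: the traced networks are 2D projections, so shells are circles of
radius $r = 0.5, 1.0, \dots$ µm (`step_um` configurable) around the
condensate centroid. A crossing is a consecutive pixel pair on one edge
path straddling the shell; a pixel exactly at distance $r$ counts as
outside (half-open shells), so a tangent path does not cross. Tortuous
edges crossing a shell several times count once per crossing, and a path
that runs tip–hub–tip contributes its crossings on both sides. A
brute-force per-pixel oracle reproduces these counts exactly in the test
suite.

Between-condition comparison fits the linear mixed model
`intersections ~ condition × radius + (1 | profile)` (random intercept per
condensate) and reports the condition main effect with the Satterthwaite
approximation. Sholl counts are small integers and profiles short, so the
fit is frequently singular for small samples; the fallback — used
automatically, or on request — is a permutation test (≥ 1999 label
shuffles) on the per-profile area under the Sholl curve.

## Node morphometrics

Connected components of the network mask are candidate nodes. Touching
blobs are split by the watershed transform of the distance map with
h-maxima suppression (`h_px = 2`): rather than splitting only "the largest"
nodes above an arbitrary size cutoff, suppression of shallow distance
maxima means small unimodal nodes are never split while genuinely fused
ones are. Components under `min_size_px` (default 100 px) are removed.

Ten properties per node (2D mode): volume (area, µm²), surface (perimeter,
µm), diameter (maximum Feret diameter), main/second/third axis lengths
(from the intensity-weighted inertia tensor, full axis = $4\sqrt\lambda$;
the third axis is a placeholder 0 in 2D and is dropped from transforms as
constant), mean/max/min intensity, and the median centroid-to-centroid
Euclidean distance to all other nodes (surface-to-surface distances would
be an alternative; centroids are used and documented).

For correlation heatmaps the intensity columns are min–max rescaled per
dataset before concatenation, then all ten properties are correlated
(Pearson). Zero-variance columns produce `NA` markers, never silent
zeros. For clustering and PCA the matrix is log10-transformed first (offset
$10^{-6}$ of each column's smallest positive value) and the log-intensity
columns are then min–max rescaled per dataset; doing the rescale *after*
the log matters, because min–max first would push the dimmest values onto
the offset and let the log magnify acquisition noise into spurious
clusters. k-means runs for each $k$ in 2…8 with 10 restarts under a
recorded seed, and the mean silhouette width selects $k$. The number of
clusters is a property of the dataset, not of the method; on synthetic
tables the chosen $k$ equals whatever was planted.

## Enrichment kinetics

Stage drift is estimated per frame by FFT cross-correlation against a
reference frame with quadratic subpixel peak interpolation (pure
translation — the rotation-free model matches typical time-lapse drift),
and frames are realigned bilinearly, with uncovered pixels set to `NA` so
an ROI drifting out of frame fails loudly. The ROI time series is the mean
intensity per frame, background-subtracted (frame-1 mean outside the ROI)
and normalized to the series maximum — the Gompertz family is closed under
scaling, so this normalizer changes $Y_M$ and $Y_0$ but not $K$;
`normalize = "none"` is available.

The growth law is

$$Y(X) = Y_M\,(Y_0/Y_M)^{\exp(-KX)}$$

with $Y(0) = Y_0$, $Y(\infty) = Y_M$, and rate constant $K$ (min⁻¹;
$1/K$ is the characteristic enrichment time). Fitting uses
Levenberg–Marquardt least squares with positivity bounds, initialized from
the series maximum ($Y_M$), the first value floored at $10^{-3}$ ($Y_0$),
and the reciprocal time-to-half-plateau ($K$). Noiseless model samples are
recovered to ≤ 10⁻⁶ relative error across a decade grid in each parameter,
and $R^2$ is 1 to at least six decimals. `baseline_correct()` is the
scalar-subtraction arithmetic used for plate-reader (pyrene/turbidity)
series.

## Bouton, ring and density quantification

Marker-positive ROIs come from Gaussian smoothing (sigma 1 px) plus Otsu —
a deliberately simple automatic mask standing in for unnamed built-in
mask functions in imaging macros — AND-ed with the GFP channel's mask in
rescue conditions, with optional extra minimum-intensity floors for noisy
expansion data. ROIs with circularity $4\pi A/P^2$ below a threshold
(default 0.5) can be re-split by watershed to separate fused boutons.
Actin enrichment per ROI is the ROI's maximum actin intensity divided by
the whole-image actin maximum (scale invariant by construction),
summarized as the per-image median.

Axial ring periodicity uses the mean-subtracted, variance-normalized
autocorrelation of a line profile; the dominant period is the lag of the
first local maximum after zero. Significance requires that maximum to
exceed a white-noise band corrected for the number of lags examined
(Bonferroni on the per-lag $1/\sqrt n$ null sd) — the uncorrected per-lag
band is crossed by pure noise somewhere almost surely once hundreds of
lags are scanned.

Cluster density counts connected components above a raw-intensity
threshold (strict `>`, default 4000 counts) with area strictly above a
pixel threshold (default 10 px) inside an axon mask, divided by the mask
area. The axon mask is supplied by the caller; for the synthetic scenes it
is part of the ground truth.

`compare_groups()` implements the shared statistics: per-group outlier
removal (iterative Grubbs at α = 0.05, ROUT, or none), a Shapiro–Wilk
normality gate at α = 0.05 per group, then a two-sided Mann–Whitney U test
if either group rejects normality and Welch's t-test otherwise.
Mann–Whitney uses exact enumeration for tie-free samples of ≤ 20 per
group and the tie-corrected normal approximation with continuity
correction otherwise, so two identical samples give p = 1. Calibration is
verified by simulation: the null rejection rate over 1000 repeats lies in
[0.03, 0.07] at α = 0.05.

## What the synthetic scenes emulate — and what they do not

The generators plant known truth with the statistical structure each
stage assumes: non-overlapping PSF-blurred disks whose in/out intensity
ratio equals the requested $K_p$ exactly before noise; asters with
straight 2-px Gaussian-profile filaments at jittered-uniform angles
(filament count and length distributions are free knobs, not literature
claims); sinusoidal ring profiles (0.19 µm period at 20 nm sampling by
default); a Gompertz-driven condensate movie with rigid, possibly
subpixel drift; two-channel bouton scenes with a known enriched subset;
and double-threshold cluster scenes built around the (4000 counts, 10 px)
cut. Noise is additive Gaussian, specified relative to the dilute level.

They deliberately omit: condensate coarsening and fusion, filament
curvature and mechanics, torus-shaped rim enrichment dynamics, detector
shot noise (a Poisson option exists scientifically but real calibration
would be needed), uneven illumination, and any 3D structure. Passing
tests therefore demonstrate the *quantification* chain is correct on data
satisfying its assumptions — not that the assumptions hold for any given
microscope.

## Problem sizes and runtime choices

The validation suite runs entirely on synthetic data at sizes chosen so
that the whole suite finishes in well under a minute of CPU: condensate
fields of 192², asters of 128², 36-frame 96×64 movies, 500-point ring
profiles, 100-series Monte-Carlo recovery, and 1000-repeat calibration of
the two-group test. These are the package's reference problem sizes; all
scale linearly in pixel count.

## Known limitations

* Tracing is 2D; z-stacks must be projected first.
* Topological thinning shortens free fibril ends by about half the local
  width, biasing total length slightly downward (≈ 2–4% on the synthetic
  asters).
* The watershed split has no notion of intensity saddles; two fused nodes
  with a single distance-transform maximum are not separated.
* The ROUT implementation assumes the constant model (a single sample's
  location), which is its only use here.
* `compare_sholl_lmm` treats shells as independent residuals given the
  random intercept; strongly autocorrelated profiles inflate the mixed
  model's optimism, which is why the permutation fallback exists.
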