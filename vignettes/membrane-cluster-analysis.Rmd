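---
title: "Quantifying two-dimensional phase separation on supported lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-dimensional phase separation on supported lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puncta)
```

## The system and the measurements

Multivalent adaptor proteins can crosslink membrane-attached receptors into a
two-dimensional polymer network. Above a critical solution concentration of
the crosslinking species, the receptor phase-separates on the membrane into
micrometer-sized clusters that are several-fold enriched in protein relative
to the surrounding bilayer. `puncta` implements the quantitative image and
kinetic analyses used to characterize this transition from TIRF images of
supported lipid bilayers (SLBs):

* **Image correction** — per-pixel background subtraction and flat-field
  (uneven illumination/detector sensitivity) division, plus rolling-ball
  local-background flattening.
* **Cluster detection** — histogram thresholding (triangle, maximum-entropy,
  or iterative 3-SD) followed by 8-connected component labeling with
  per-cluster areas, intensities, centroids, and edge flags.
* **Order parameters** — the fraction of total membrane fluorescence residing
  in clusters, and the pixel-intensity variance; both rise sharply at the
  clustering (critical) concentration, which is estimated by breakpoint
  fitting on titration curves.
* **Cluster statistics** — exponential versus power-law discrimination of the
  cluster size distribution, and quadrat (box) counts with an edge-cluster
  correction and Gaussian fit testing spatial randomness.
* **Kinetics** — FRAP normalization and single/double-exponential fitting with
  nested-model F-tests, membrane-dissociation decays, and per-cluster
  actin-assembly half-times.
* **Density calibration** — conversion of fluorescence to absolute surface
  density (molecules/µm²) via the brightness correction factor
  `F = I_labeled_protein / I_labeled_SUV` and a fluorescent-lipid standard
  curve.

Because no public raw-image data accompany this system, every analysis stage
is validated against a first-class synthetic-data module whose ground truth is
known by construction.

## The synthetic-data generator

`gen_bilayer_image()` renders a TIRF-like field as

```
image = vignette × background × (1 + (E − 1) × mask) + offset + noise,
```

where `E` is the cluster enrichment (default 4, the enrichment observed for
clustered receptor), the vignette is a radially symmetric quadratic falloff,
and the noise is additive Gaussian (a camera read-noise proxy). Two cluster
morphologies reproduce the two regimes of two-dimensional phase separation:

* **nucleated** — discrete puncta; centers from a homogeneous Poisson process
  (`cluster_density` per µm²), areas from an exponential law
  (`mean_cluster_area`), each rendered as an irregular blob with exactly the
  drawn pixel area;
* **spinodal** — a labyrinthine, field-spanning pattern from thresholding a
  Gaussian random field (correlation length `correlation_length`) at the
  quantile giving `clustered_fraction`.

```{r}
sc <- gen_bilayer_image(scene_params(width = 256, height = 256,
  morphology = "nucleated", seed = 1))
mean(sc$mask)                 # clustered area fraction
head(sc$clusters, 3)          # per-cluster ground truth
```

`gen_titration()` produces an image series whose clustered area fraction is 0
below the critical concentration `c*` and
`max_clustered_fraction × (1 − exp(−(c − c*)/rise_width))` above it.
`gen_frap_trace()`, `gen_dissociation_trace()`, `gen_calibration()` and
`gen_actin_timecourse()` provide kinetic traces and calibration standards with
recorded truth. All generators are bit-reproducible from their `seed`.

### What the generator does and does not emulate

The generator reproduces the statistical structure the analyses rely on:
Poisson cluster placement, an exponential size law, a sharp clustering onset,
mono/bi-exponential recovery with acquisition bleaching, linear fluorescence
standards, and stochastic actin lags drawn independently of cluster size. It
deliberately omits Poisson shot noise (read noise only), cluster growth
dynamics and coalescence, diffusion-coupled FRAP profiles, and any physical
model of the multivalent bond network. Tests passing on these data therefore
certify the *analysis chain* — correction, segmentation, statistics, fitting —
not the biophysics of real membranes.

## Defaults and the reasoning behind them

* **Field geometry**: 512 × 512 px at 0.16 µm/px, so a 56 × 56 µm analysis
  region is 350 px across. Camera bit depth, magnification and pixel size are
  not derivable from the source experiments; these are chosen, not inferred.
* **Enrichment 4** and **critical concentration 200 nM** follow the
  measured fourfold cluster enrichment and the observed clustering onset.
* **Titration shape** (`rise_width = 3000` nM, `max_clustered_fraction =
  0.25`): the clustered fraction rises gradually and near-linearly across a
  25–1000 nM titration, with the fractional intensity reaching roughly 0.2 at
  1 µM, as in the published titrations. This choice also matters
  statistically: the breakpoint estimator fits a *linear* rising segment, so
  it is an unbiased estimate of "the concentration at which the order
  parameter begins increasing" only while the rise is approximately linear.
  On strongly saturating curves the same estimator is intrinsically biased
  early by one to two grid points — a property of the estimator, computable
  from the noiseless closed-form curve, not of the noise.
* **Cluster density 0.1/µm², mean area 0.5 µm²**: about 300 clusters in a
  56 × 56 µm region at ~5% area fraction, typical of nucleated fields.
* **Histogram bins 256**, **8-connectivity**, **min cluster area 4 px**:
  ImageJ-style conventions; the minimum area suppresses single-pixel noise.
* **Thresholds on raw intensities**: histograms are built on the raw
  (floating-point) data with no 8-bit conversion.
* **Flat-field reference smoothing**: the homogeneous-bilayer reference is
  median-filtered (radius 3 px) before normalization so single hot pixels do
  not set the maximum; correction factors are floored at 0.01 and pixels
  below the floor flagged rather than amplified.
* **Rolling ball**: grayscale opening with a flat disc (default radius
  50 px); the paraboloid variant is out of scope.
* **FRAP multistart**: bi-exponential fits are initialization-sensitive, so
  fits start from a τ grid `{T/100, T/10, T/3}` crossed with amplitude
  fractions `{0.25, 0.5, 0.75}`, plus starts derived from the
  single-component solution; the smallest-SS fit is kept. The raw
  Levenberg–Marquardt optimizer is used because collapsed solutions (equal
  time constants, or an amplitude at its zero bound) are legitimate
  least-squares optima with rank-deficient Jacobians.
* **Actin half-times**: analysis window 27 min; `t½` is found by linear
  interpolation between the frames bracketing half-maximum after baseline
  subtraction; traces never exceeding twice baseline are flagged rather than
  assigned a half-time.
* **Leaflets**: the mole-percent-to-density conversion counts both bilayer
  leaflets (the published density range for 0.05–0.4 mol% fluorescent lipid
  at a 69 Å² headgroup is consistent with two leaflets; single-leaflet
  accounting would halve it). The leaflet count is a parameter.

## Order parameters and breakpoint detection

`titration_statistics()` computes, per concentration, the fractional
intensity in clusters and the signal variance (plus the dimensionless CV² as
an illumination-robust companion; the variance of a raw vignetted image
reflects the illumination profile, so order parameters are meant to be
computed on flat-field-corrected images).

A cluster-free image has no bimodal intensity structure, so any histogram
threshold merely splits the noise distribution; at 8-connectivity the
resulting mask percolates into a giant pseudo-cluster covering much of the
field. Such images are recognized by their lack of contrast — the mean
intensity of thresholded regions is within a few percent of the background,
whereas genuine clusters are several-fold brighter — and recorded as
fractional intensity 0 (`min_contrast = 1.5`).

```{r}
conc <- round(exp(seq(log(25), log(1000), length.out = 12)), 1)
ts <- gen_titration(titration_params(conc,
  scene = scene_params(width = 192, height = 192, vignette_strength = 0,
                       seed = 7)))
curve <- titration_statistics(ts, method = "triangle")
curve[, c("concentration", "fractional_intensity", "variance")]
clustering_concentration(curve, "fractional_intensity")
```

"Begin increasing" is operationalized two ways: the primary `hockey_stick`
method least-squares fits a flat baseline joined to a rising linear segment
(breakpoint scanned over the interior grid points; detection requires a
positive post-break slope at p < 0.05 and an F-test win over the flat model),
and the secondary `baseline_3sd` method reports the first concentration
exceeding the baseline mean + 3 SD. On 12-point log-spaced titrations the
breakpoint resolution is one grid step; estimates should agree between the
triangle and maximum-entropy thresholds, which is asserted in the test suite.

## Size and spatial statistics

Size distributions are built from non-edge clusters on a linear area axis
(Freedman–Diaconis bin width by default, floored at one pixel area).
`fit_size_model()` fits straight lines to (size, log count) and (log size,
log count) over occupied bins, weighting bins by their counts — the standard
variance-stabilizing weighting for log counts, without which sparse tail bins
dominate — and prefers the model with the higher r² by a margin of 0.02.
Zero-count bins are excluded from the log-space fits. Maximum-likelihood
power-law fitting with cutoff estimation is deliberately out of scope; the
regression-on-log-counts procedure is the method under study, with a direct
nonlinear exponential fit as a cross-check.

`box_counts()` divides the label map into 5 × 5 boxes and counts clusters per
box twice, including and excluding clusters that intersect the box boundary.
A cluster spanning k boxes is counted k times in the "including" tally; half
the average per-box excess is subtracted from each box, which removes the
double counting exactly in aggregate. Two distinct edge definitions coexist
deliberately: size analysis excludes clusters touching the *image* border,
box analysis corrects for clusters crossing *box* boundaries.

`fit_gaussian_counts()` fits a Gaussian to the relative-frequency histogram
of corrected counts. One numerical property matters for test design: a
least-squares Gaussian fitted to Poisson-distributed counts inherits a skew
bias of about −0.25 counts in its mean, independent of the mean itself, so
mean-recovery at the percent level requires per-box means of several tens.
The spatial-randomness test therefore uses 93 regions of 350 × 350 px with a
cluster density giving ≈ 50 clusters per box.

## Kinetics

`normalize_frap()` background-subtracts, divides by the (equally corrected)
acquisition-bleaching reference trace, and scales the pre-bleach mean to 1;
additive reference removal is available as `mode = "subtract"`. Traces carry
an explicit pre-bleach frame count; for raw traces without one,
`find_bleach_frame()` locates the first frame dropping more than 3 SD below
the running pre-bleach mean. `fit_recovery()` fits
`plateau − Σ Aᵢ exp(−t/τᵢ)` from the first post-bleach frame, so results are
invariant to time-axis shifts and to global intensity rescaling.
`select_model()` applies the textbook nested-model F-test
`F = [(SS₁−SS₂)/(df₁−df₂)]/(SS₂/df₂)`; a perfect richer fit (SS₂ = 0) is
reported as preferred with a flag rather than a division error. Amplitudes
are reported as fractions of the total recovering amplitude. Drift
correction is out of scope: the package accepts pre-extracted ROI traces
(the original workflow aligned images with a feature-based plugin before
extraction).

```{r}
p <- frap_gen_params(c(86, 526), c(0.76, 0.24), bleach_depth = 0.8,
                     frame_interval = 2, duration = 2000, noise_sd = 0.01,
                     seed = 2)
nt <- normalize_frap(gen_frap_trace(p))
f2 <- fit_recovery(nt, 2)
f2
select_model(fit_recovery(nt, 1), f2)
```

Degenerate inputs are flagged, not silently fit: constant recovery traces
raise an error (zero recovering amplitude), constant decay traces return
`tau = NA` with an `"unidentifiable"` flag, and fitted time constants at
their bounds set a flag on the result.

## Density calibration

`correction_factor()` forms `F` from the solution standard-curve slopes of
labeled protein and fluorescent lipid; `intensity_to_density()` divides a
measured intensity by `F`, inverts the bilayer standard curve (intercept
retained; forcing through the origin is an option), and divides by the
labeled fraction to report total molecules/µm². Guard rails follow the
verified linear range: intensities beyond 1.5× the largest standard are
refused, labeled fractions above 60% warn (quantitative work used ≤ 15%
labeling), and negative inverted densities raise an error since they signal
background mis-subtraction.

```{r}
cal <- build_calibration(gen_calibration(noise_sd = 0, seed = 1),
                         labeled_fraction = 0.15)
molpercent_to_density(0.004)                        # 0.4 mol% standard
intensity_to_density(density_to_intensity(2700, cal), cal)
```

## Problem sizes used in the test suite

Simulations in the tests are sized to exercise each statistical claim at its
stated power while remaining quick: titration breakpoint behavior uses 100
seeds of 12-concentration series on 256² px scenes; spatial statistics use 93
regions of 350² px; size-law discrimination uses 50 seeds of 500 clusters;
the F-test type-I rate uses 200 single-exponential traces; threshold
implementations are checked against exhaustive brute-force search on 1000
random histograms. Breakpoint analyses are run on vignette-free scenes,
equivalent to the flat-field-corrected images the protocol prescribes; the
correction path itself is tested separately against the generator's known
vignette field.

## Known limitations

* Additive Gaussian noise only; no shot noise, so very-low-signal behavior of
  the thresholding methods is not exercised.
* No watershed splitting of merged clusters and no frame-to-frame tracking;
  coalescence events are not lineage-traced.
* Asymptotic (±1.96 SE) confidence intervals on kinetic parameters; no
  bootstrap.
* The breakpoint estimator assumes the order parameter is near-linear just
  above onset; on strongly saturating titrations it reports the onset early
  (see above), and the `baseline_3sd` method is the more robust choice.
* Per-trace FRAP fitting by default; pooled fitting across replicates (which
  produces the large residual degrees of freedom seen in pooled published
  fits) is not implemented.
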