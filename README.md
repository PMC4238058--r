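# puncta

Quantitative analysis of protein clusters on supported lipid bilayers.

## What it is for

When a membrane-attached receptor is crosslinked by multivalent cytoplasmic
partners, it can undergo a two-dimensional phase transition: above a critical
solution concentration of the crosslinker, the receptor condenses into
micrometer-sized, several-fold-enriched clusters on the bilayer. `puncta` is
an R toolkit for quantifying that transition from TIRF images of supported
lipid bilayers (SLBs) and from the associated kinetic measurements. It is
aimed at membrane biophysicists and reconstitution labs analyzing:

* **titrations** — when do clusters appear, and how much material is in them?
* **cluster statistics** — are clusters placed randomly, and is their size
  law exponential (stochastic nucleation) or a power law (coalescence)?
* **kinetics** — FRAP exchange rates, membrane dissociation, and the timing
  of actin assembly on clusters;
* **absolute densities** — converting fluorescence to molecules/µm².

## The quantities it computes

Clusters are the bright regions of a corrected image above a histogram
threshold (triangle, maximum-entropy, or iterative 3-SD rule). Two order
parameters track the phase transition as a function of crosslinker
concentration *c*:

* fractional intensity in clusters
  *f*(c) = Σ<sub>cluster px</sub> I / Σ<sub>all px</sub> I,
* signal variance Var[I] across the bilayer image,

and the clustering (critical) concentration is the breakpoint where they
begin increasing, estimated by least squares with a flat-baseline +
rising-linear-segment ("hockey stick") model plus an F-test against the flat
model.

FRAP recoveries are normalized to pre-bleach intensity and fit with
*f*(t) = plateau − Σᵢ Aᵢ exp(−t/τᵢ) for one or two components; the models are
compared with the nested-model F-test
F = [(SS₁−SS₂)/(df₁−df₂)] / (SS₂/df₂). Surface densities follow from the
brightness correction factor F = I<sub>labeled protein</sub> /
I<sub>labeled SUV</sub> and a fluorescent-lipid standard curve, with
mole fractions converted through density = fraction × leaflets ×
10⁸ Å²µm⁻² / headgroup area (69 Å² default).

A first-class synthetic-data module (`gen_bilayer_image()`,
`gen_titration()`, `gen_frap_trace()`, `gen_calibration()`,
`gen_actin_timecourse()`) generates TIRF-like inputs with known ground truth,
so the whole pipeline is testable without microscope data.

## Worked example

```r
library(puncta)

## a synthetic nucleated field: 256 x 256 px, fourfold-enriched clusters
sc  <- gen_bilayer_image(scene_params(width = 256, height = 256,
         morphology = "nucleated", vignette_strength = 0, seed = 1))
thr <- compute_threshold(sc$image, "triangle")
cl  <- segment_clusters(sc$image, thr)
cl
#> labeled_clusters: 122 clusters (threshold 1174)
#>   area 0.102-3.35 um^2, 5 touching the image edge
fractional_intensity(sc$image, cl)
#> [1] 0.1467
enrichment_ratio(sc$image, cl)$ratio
#> [1] 3.72

## FRAP of clustered receptor: tau = 86 s / 526 s, fractions 76% / 24%
p  <- frap_gen_params(c(86, 526), c(0.76, 0.24), bleach_depth = 0.8,
        frame_interval = 2, duration = 2000, noise_sd = 0.01, seed = 2)
nt <- normalize_frap(gen_frap_trace(p))
f2 <- fit_recovery(nt, 2)
f2
#> 2-component exponential recovery fit
#>   tau1 = 86.82 (76%)
#>   tau2 = 510.1 (24%)
#>   plateau 0.9973, SS 0.1017, df 996
select_model(fit_recovery(nt, 1), f2)
#> F (2, 996) = 1459, p = 1.12e-296 -> preferred model: double

## absolute density of a 0.4 mol% fluorescent-lipid standard
molpercent_to_density(0.004)
#> [1] 11594.2
```

The segmentation recovers the generated clusters (14.7% of the fluorescence
in clusters at ~3.7-fold apparent enrichment — slightly below the true
fourfold because threshold-selected pixels exclude dim cluster rims); the
bi-exponential fit recovers the generating time constants within a few
percent and the F-test overwhelmingly prefers the two-component model, and
the mole-percent conversion gives 11,594 molecules/µm² for 0.4 mol% at a
69 Å² headgroup counting both leaflets.

For titration analysis, build a curve and estimate the clustering
concentration:

```r
conc  <- round(exp(seq(log(25), log(1000), length.out = 12)), 1)
ts    <- gen_titration(titration_params(conc,
           scene = scene_params(vignette_strength = 0, seed = 7)))
curve <- titration_statistics(ts, method = "triangle")
clustering_concentration(curve, "fractional_intensity")
```

TIFF input/output (`read_stack()`, `write_stack()`), YAML configuration
(`load_config()`) and a manifest-driven end-to-end runner (`run_pipeline()`)
tie the stages into a reproducible workflow; see the vignette in
`vignettes/membrane-cluster-analysis.Rmd` for the methods, parameter
defaults, and design rationale.

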