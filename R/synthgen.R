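#' Parameters for a synthetic bilayer scene
#'
#' Describes a single TIRF-like image of a supported lipid bilayer carrying a
#' fluorescent membrane-attached protein. The scene is a homogeneous fluid
#' background optionally decorated with clustered (phase-separated) regions in
#' one of two morphologies: `"nucleated"` (discrete, irregular puncta whose
#' areas follow an exponential law and whose centers are placed by a
#' homogeneous Poisson process) or `"spinodal"` (a system-spanning labyrinthine
#' pattern obtained by thresholding a smoothed Gaussian random field).
#' Clustered pixels are `enrichment`-fold brighter than the surrounding
#' bilayer; the default of 4 matches the enrichment observed for clustered
#' receptor on bilayers. Optics and camera are modelled as a radially
#' symmetric quadratic vignette, a constant camera offset, and additive
#' Gaussian read noise (shot noise is deliberately omitted; see the vignette).
#'
#' @param width,height image size in pixels.
#' @param pixel_size um per pixel.
#' @param mean_intensity mean background (non-clustered bilayer) fluorescence
#'   in counts, before vignetting and offset; must be positive.
#' @param camera_offset constant detector offset in counts.
#' @param noise_sd standard deviation of additive Gaussian noise (counts).
#' @param vignette_strength relative intensity falloff at the image corner,
#'   in `[0, 1)`; 0 disables vignetting.
#' @param morphology `"none"`, `"nucleated"`, or `"spinodal"`.
#' @param enrichment fold-enrichment of cluster over background density
#'   (>= 1).
#' @param cluster_density expected number of clusters per um^2 (nucleated).
#' @param mean_cluster_area mean of the exponential cluster-area law, um^2
#'   (nucleated).
#' @param irregularity expected number of extra lobes per cluster; 0 gives
#'   near-circular puncta (nucleated).
#' @param correlation_length correlation length of the spinodal pattern, um.
#' @param clustered_fraction area fraction covered by clusters, in `[0, 1]`
#'   (spinodal).
#' @param conserve_mean if `TRUE`, the background level is lowered so that the
#'   mean protein density over the whole field equals `mean_intensity`
#'   (protein conservation on clustering). Off by default: experimentally the
#'   average density is unchanged during a titration.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A validated list of class `scene_params`.
#' @seealso [gen_bilayer_image()]
#' @export
scene_params <- function(width = 512L, height = 512L, pixel_size = 0.16,
                         mean_intensity = 1000, camera_offset = 100,
                         noise_sd = 20, vignette_strength = 0.2,
                         morphology = c("none", "nucleated", "spinodal"),
                         enrichment = 4, cluster_density = 0.1,
                         mean_cluster_area = 0.5, irregularity = 1,
                         correlation_length = 2, clustered_fraction = 0.3,
                         conserve_mean = FALSE, seed = 1L) {
  morphology <- match.arg(morphology)
  if (width < 1 || height < 1) stop("image dimensions must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (mean_intensity <= 0) stop("mean_intensity must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (vignette_strength < 0 || vignette_strength >= 1)
    stop("vignette_strength must be in [0, 1)")
  if (enrichment < 1) stop("enrichment must be >= 1")
  if (cluster_density < 0) stop("cluster_density must be non-negative")
  if (mean_cluster_area <= 0) stop("mean_cluster_area must be positive")
  if (irregularity < 0) stop("irregularity must be non-negative")
  if (correlation_length <= 0) stop("correlation_length must be positive")
  if (clustered_fraction < 0 || clustered_fraction > 1)
    stop("clustered_fraction must be in [0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, mean_intensity = mean_intensity,
                 camera_offset = camera_offset, noise_sd = noise_sd,
                 vignette_strength = vignette_strength, morphology = morphology,
                 enrichment = enrichment, cluster_density = cluster_density,
                 mean_cluster_area = mean_cluster_area,
                 irregularity = irregularity,
                 correlation_length = correlation_length,
                 clustered_fraction = clustered_fraction,
                 conserve_mean = conserve_mean, seed = as.integer(seed)),
            class = "scene_params")
}

# Radially symmetric quadratic vignette field with maximum 1 at the center.
vignette_field <- function(nr, nc, strength) {
  if (strength <= 0) return(matrix(1, nr, nc))
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
  1 - strength * r2 / max(r2)
}

# Pixels of one irregular cluster: top-k pixels of a smooth random blob field,
# guaranteeing the realized in-field area equals min(k, window size) pixels
# (clipped at the image border). Returns linear (column-major) pixel indices.
blob_pixels <- function(cx, cy, k, irregularity, nr, nc) {
  r0 <- sqrt(k / pi)
  hw <- max(2L, ceiling(2.5 * r0) + 2L)
  rows <- max(1L, round(cy) - hw):min(nr, round(cy) + hw)
  cols <- max(1L, round(cx) - hw):min(nc, round(cx) + hw)
  g <- 1L + stats::rpois(1L, irregularity)
  bx <- cx + stats::rnorm(g, 0, 0.35 * r0)
  by <- cy + stats::rnorm(g, 0, 0.35 * r0)
  sig2 <- 2 * (0.9 * r0)^2
  f <- matrix(0, length(rows), length(cols))
  for (j in seq_len(g))
    f <- f + exp(-(outer((rows - by[j])^2, (cols - bx[j])^2, "+")) / sig2)
  k <- min(k, length(f))
  sel <- order(f, decreasing = TRUE)[seq_len(k)]
  lr <- (sel - 1L) %% length(rows) + 1L
  lc <- (sel - 1L) %/% length(rows) + 1L
  (cols[lc] - 1L) * nr + rows[lr]
}

#' Generate a synthetic bilayer image with ground truth
#'
#' Renders a TIRF-like image according to
#' `vignette x background x (1 + (enrichment - 1) x mask) + offset + noise`,
#' together with the ground-truth cluster mask and a per-cluster truth table.
#' Nucleated morphology draws the number of clusters from a Poisson law with
#' intensity `cluster_density` per um^2, cluster areas from an exponential law
#' with mean `mean_cluster_area`, and renders each cluster as an irregular
#' blob with exactly the drawn pixel area (clipped at the image border).
#' Spinodal morphology thresholds a Gaussian random field smoothed to
#' `correlation_length` at the quantile giving `clustered_fraction`.
#'
#' @param params a [scene_params()] object.
#' @return A list of class `bilayer_scene` with elements `image`
#'   (a [raster_image()]), `mask` (logical ground-truth matrix), `clusters`
#'   (data frame of seeded clusters: center `x`/`y` in 0-based pixel
#'   coordinates, `target_area_px`, realized `area_px` and `area_um2`), and
#'   `params`.
#' @examples
#' sc <- gen_bilayer_image(scene_params(width = 64, height = 64,
#'   morphology = "nucleated", noise_sd = 0, seed = 7))
#' mean(sc$mask)
#' @export
gen_bilayer_image <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  p <- params
  set.seed(p$seed)
  nr <- p$height; nc <- p$width
  mask <- matrix(FALSE, nr, nc)
  truth <- data.frame(x = numeric(0), y = numeric(0),
                      target_area_px = integer(0), area_px = integer(0),
                      area_um2 = numeric(0))
  if (p$morphology == "nucleated") {
    field_um2 <- nr * nc * p$pixel_size^2
    n <- stats::rpois(1L, p$cluster_density * field_um2)
    if (n > 0) {
      cx <- stats::runif(n, 0.5, nc + 0.5)
      cy <- stats::runif(n, 0.5, nr + 0.5)
      mean_px <- p$mean_cluster_area / p$pixel_size^2
      target <- pmax(1L, as.integer(round(stats::rexp(n, rate = 1 / mean_px))))
      realized <- integer(n)
      for (i in seq_len(n)) {
        px <- blob_pixels(cx[i], cy[i], target[i], p$irregularity, nr, nc)
        mask[px] <- TRUE
        realized[i] <- length(px)
      }
      truth <- data.frame(x = cx - 1, y = cy - 1, target_area_px = target,
                          area_px = realized,
                          area_um2 = realized * p$pixel_size^2)
    }
  } else if (p$morphology == "spinodal") {
    if (p$clustered_fraction >= 1)
      stop("clustered_fraction must be < 1 for spinodal morphology")
    if (p$clustered_fraction > 0) {
      f <- EBImage::gblur(matrix(stats::rnorm(nr * nc), nr, nc),
                          sigma = p$correlation_length / p$pixel_size)
      q <- stats::quantile(f, 1 - p$clustered_fraction, names = FALSE)
      mask <- f > q
    }
  }
  v <- vignette_field(nr, nc, p$vignette_strength)
  bg <- p$mean_intensity
  if (isTRUE(p$conserve_mean) && any(mask))
    bg <- p$mean_intensity / (1 + (p$enrichment - 1) * mean(mask))
  img <- v * (bg + mask * (p$enrichment - 1) * bg) + p$camera_offset
  if (p$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, p$noise_sd)
  structure(list(image = raster_image(img, p$pixel_size), mask = mask,
                 clusters = truth, params = p),
            class = "bilayer_scene")
}

#' Parameters for a synthetic titration series
#'
#' @param concentrations strictly increasing solution concentrations (nM) of
#'   the titrated clustering agent.
#' @param critical_concentration concentration (nM) at which clusters first
#'   appear; the default 200 nM reproduces the sharp clustering onset seen for
#'   the reconstituted receptor system.
#' @param rise_width scale (nM) of the saturating rise of clustered area
#'   fraction above the critical concentration. The default keeps the order
#'   parameters rising gradually and near-linearly across a 25-1000 nM
#'   titration, as observed experimentally; see the package vignette for the
#'   rationale.
#' @param max_clustered_fraction asymptotic clustered area fraction.
#' @param scene a [scene_params()] object used as the template for every
#'   image in the series (its `morphology`, `cluster_density` and `seed` are
#'   overridden per point).
#' @return A list of class `titration_params`.
#' @export
titration_params <- function(concentrations, critical_concentration = 200,
                             rise_width = 3000, max_clustered_fraction = 0.25,
                             scene = scene_params()) {
  if (length(concentrations) == 0) stop("empty concentration list")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  if (critical_concentration <= 0)
    stop("critical_concentration must be positive")
  if (rise_width <= 0) stop("rise_width must be positive")
  if (max_clustered_fraction < 0 || max_clustered_fraction > 1)
    stop("max_clustered_fraction must be in [0, 1]")
  if (!inherits(scene, "scene_params")) stop("scene must be a scene_params object")
  structure(list(concentrations = as.numeric(concentrations),
                 critical_concentration = critical_concentration,
                 rise_width = rise_width,
                 max_clustered_fraction = max_clustered_fraction,
                 scene = scene),
            class = "titration_params")
}

#' Ground-truth clustered area fraction of a titration
#'
#' The generator's clustered area fraction is exactly 0 below the critical
#' concentration and rises as a saturating exponential above it:
#' `phi(c) = max_clustered_fraction * (1 - exp(-(c - c*) / rise_width))`.
#'
#' @param concentration concentration(s) in nM.
#' @param params a [titration_params()] object.
#' @return Numeric vector of area fractions.
#' @export
clustered_area_fraction <- function(concentration, params) {
  cstar <- params$critical_concentration
  ifelse(concentration <= cstar, 0,
         params$max_clustered_fraction *
           (1 - exp(-(concentration - cstar) / params$rise_width)))
}

#' Generate a synthetic titration series of bilayer images
#'
#' One image per concentration. Below the critical concentration the scene is
#' a homogeneous bilayer; above it, nucleated clusters are generated with a
#' cluster density chosen so that the expected clustered area fraction equals
#' [clustered_area_fraction()] at that concentration. Per-image seeds are
#' derived deterministically from the template scene seed.
#'
#' @param params a [titration_params()] object.
#' @return A list of class `titration_scenes`; each element is a list with
#'   `concentration` and `scene` (a `bilayer_scene`). The ground-truth
#'   critical concentration and area fractions are attached as attribute
#'   `truth`.
#' @export
gen_titration <- function(params) {
  if (!inherits(params, "titration_params"))
    stop("params must be a titration_params object")
  conc <- params$concentrations
  phi <- clustered_area_fraction(conc, params)
  out <- vector("list", length(conc))
  for (i in seq_along(conc)) {
    sp <- params$scene
    sp$seed <- sp$seed + i
    if (phi[i] > 0) {
      sp$morphology <- "nucleated"
      sp$cluster_density <- phi[i] / sp$mean_cluster_area
    } else {
      sp$morphology <- "none"
    }
    class(sp) <- "scene_params"
    out[[i]] <- list(concentration = conc[i], scene = gen_bilayer_image(sp))
  }
  structure(out, class = "titration_scenes",
            truth = list(critical_concentration = params$critical_concentration,
                         clustered_fraction = phi, concentrations = conc))
}

#' Parameters for a synthetic FRAP recovery trace
#'
#' @param tau_values one or two recovery time constants (s), positive.
#' @param fractions amplitude fractions of the recovering components; must sum
#'   to 1 (within 1e-9) and match `tau_values` in length.
#' @param bleach_depth fraction of fluorescence removed by the bleach pulse,
#'   in `[0, 1]`.
#' @param mobile_fraction fraction of the bleached signal that recovers.
#' @param frame_interval acquisition interval (s).
#' @param duration post-bleach observation time (s); must exceed
#'   `frame_interval`.
#' @param acq_bleach_tau time constant (s) of mono-exponential acquisition
#'   photobleaching applied to the whole trace; `Inf` disables it.
#' @param noise_sd Gaussian noise SD in normalized intensity units.
#' @param n_prebleach number of pre-bleach frames.
#' @param seed integer seed.
#' @return A list of class `frap_gen_params`.
#' @export
frap_gen_params <- function(tau_values, fractions = rep(1 / length(tau_values),
                                                        length(tau_values)),
                            bleach_depth = 0.8, mobile_fraction = 1,
                            frame_interval = 1, duration = 300,
                            acq_bleach_tau = Inf, noise_sd = 0.01,
                            n_prebleach = 10L, seed = 1L) {
  if (!length(tau_values) %in% 1:2) stop("tau_values must have length 1 or 2")
  if (any(tau_values <= 0)) stop("time constants must be positive")
  if (length(fractions) != length(tau_values))
    stop("fractions must match tau_values in length")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (bleach_depth < 0 || bleach_depth > 1) stop("bleach_depth must be in [0, 1]")
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must be in [0, 1]")
  if (duration <= frame_interval) stop("duration must exceed frame_interval")
  if (acq_bleach_tau <= 0) stop("acq_bleach_tau must be positive (Inf allowed)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_prebleach < 2) stop("at least 2 pre-bleach frames are required")
  structure(list(tau_values = as.numeric(tau_values),
                 fractions = as.numeric(fractions),
                 bleach_depth = bleach_depth, mobile_fraction = mobile_fraction,
                 frame_interval = frame_interval, duration = duration,
                 acq_bleach_tau = acq_bleach_tau, noise_sd = noise_sd,
                 n_prebleach = as.integer(n_prebleach), seed = as.integer(seed)),
            class = "frap_gen_params")
}

# Noiseless normalized FRAP recovery law, time measured from the bleach.
frap_recovery_law <- function(s, p) {
  rec <- rowSums(vapply(seq_along(p$tau_values), function(i)
    p$fractions[i] * (1 - exp(-s / p$tau_values[i])), numeric(length(s))))
  (1 - p$bleach_depth) + p$bleach_depth * p$mobile_fraction * rec
}

#' Generate a synthetic FRAP trace
#'
#' Pre-bleach frames sit at normalized intensity 1; post-bleach frames follow
#' `f(s) = (1 - bleach_depth) + bleach_depth * mobile_fraction *
#' sum_i f_i (1 - exp(-s / tau_i))` with `s` measured from the bleach. The
#' whole trace is multiplied by the acquisition-bleaching factor
#' `exp(-t / acq_bleach_tau)` (absolute time `t`), which is also returned as
#' the noiseless reference trace for normalization.
#'
#' @param params a [frap_gen_params()] object.
#' @return A [kinetic_trace()] whose `reference` element holds the noiseless
#'   acquisition-bleach trace; the generating parameters are attached as
#'   attribute `truth`.
#' @export
gen_frap_trace <- function(params) {
  if (!inherits(params, "frap_gen_params"))
    stop("params must be a frap_gen_params object")
  p <- params
  set.seed(p$seed)
  dt <- p$frame_interval
  n_post <- floor(p$duration / dt) + 1L
  times <- seq(0, by = dt, length.out = p$n_prebleach + n_post)
  t_bleach <- p$n_prebleach * dt
  base <- c(rep(1, p$n_prebleach),
            frap_recovery_law(times[(p$n_prebleach + 1):length(times)] - t_bleach, p))
  acq <- if (is.finite(p$acq_bleach_tau)) exp(-times / p$acq_bleach_tau)
         else rep(1, length(times))
  values <- base * acq
  if (p$noise_sd > 0) values <- values + stats::rnorm(length(values), 0, p$noise_sd)
  tr <- kinetic_trace(times, values, n_prebleach = p$n_prebleach,
                      reference = acq, background = 0, time_unit = "s")
  attr(tr, "truth") <- p
  tr
}

#' Generate a synthetic membrane-dissociation decay
#'
#' Mono-exponential loss of membrane-bound fluorescence,
#' `I(t) = amplitude * exp(-t / tau) + offset + noise`, as observed when
#' His-tagged protein slowly dissociates from a supported bilayer.
#'
#' @param tau dissociation time constant (s).
#' @param amplitude,offset decay amplitude and final plateau.
#' @param frame_interval,duration sampling interval and total time (s).
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return A [kinetic_trace()] with no pre-bleach frames; generating
#'   parameters attached as attribute `truth`.
#' @export
gen_dissociation_trace <- function(tau = 2080, amplitude = 1, offset = 0,
                                   frame_interval = 60, duration = 6000,
                                   noise_sd = 0.01, seed = 1L) {
  if (tau <= 0) stop("tau must be positive")
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = frame_interval)
  values <- amplitude * exp(-times / tau) + offset
  if (noise_sd > 0) values <- values + stats::rnorm(length(values), 0, noise_sd)
  tr <- kinetic_trace(times, values, n_prebleach = 0L, time_unit = "s")
  attr(tr, "truth") <- list(tau = tau, amplitude = amplitude, offset = offset)
  tr
}

#' Generate synthetic fluorescence calibration standards
#'
#' Three linear standard point sets: fluorescent lipid in solution (intensity
#' vs concentration), labeled protein in solution (intensity vs
#' concentration), and fluorescent lipid on supported bilayers (intensity vs
#' surface density). Gaussian scatter is applied multiplicatively so a
#' relative `noise_sd` behaves uniformly across the dynamic range. All lines
#' pass through the origin, as observed for the real standards.
#'
#' @param dye_slope,protein_slope intensity per nM for the solution standards.
#' @param bilayer_slope intensity per molecule/um^2 for the bilayer standard.
#' @param noise_sd relative Gaussian scatter (e.g. 0.02 for 2%).
#' @param n_points points per standard (>= 2).
#' @param seed integer seed.
#' @return A list of class `calibration_dataset` with data frames `dye`,
#'   `protein`, `bilayer` (columns `x`, `intensity`) and a `truth` list
#'   holding the slopes and the true correction factor
#'   `F = protein_slope / dye_slope`.
#' @export
gen_calibration <- function(dye_slope = 1000, protein_slope = 2000,
                            bilayer_slope = 0.5, noise_sd = 0.02,
                            n_points = 8L, seed = 1L) {
  if (dye_slope <= 0 || protein_slope <= 0 || bilayer_slope <= 0)
    stop("slopes must be positive")
  if (n_points < 2) stop("n_points must be at least 2")
  set.seed(as.integer(seed))
  mk <- function(x, slope) {
    y <- slope * x
    if (noise_sd > 0) y <- y * (1 + stats::rnorm(length(x), 0, noise_sd))
    data.frame(x = x, intensity = y)
  }
  structure(list(dye = mk(seq(25, 400, length.out = n_points), dye_slope),
                 protein = mk(seq(25, 400, length.out = n_points), protein_slope),
                 bilayer = mk(seq(1000, 12000, length.out = n_points),
                              bilayer_slope),
                 truth = list(dye_slope = dye_slope,
                              protein_slope = protein_slope,
                              bilayer_slope = bilayer_slope,
                              F = protein_slope / dye_slope)),
            class = "calibration_dataset")
}

#' Generate synthetic per-cluster actin assembly time courses
#'
#' Each cluster shows a small uniform baseline of recruited actin followed by
#' a saturating rise `baseline + plateau * (1 - exp(-(t - lag) / rise_tau))`
#' starting at a lag drawn uniformly from `lag_range`, emulating the
#' stochastic onset of Arp2/3-dependent filament assembly on clusters. Lags
#' are drawn independently of the cluster's area and receptor intensity, which
#' are also returned, so the generated data carry no lag-size correlation.
#'
#' @param n_clusters number of clusters.
#' @param lag_range two-element range (min) of the uniform lag law.
#' @param rise_tau time constant (min) of the saturating rise.
#' @param frame_interval,duration sampling interval and total time (min);
#'   the 3-min default matches typical TIRF time-lapse acquisition.
#' @param plateau,baseline rise amplitude and pre-assembly baseline.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return A list of class `actin_dataset`: `traces` (list of
#'   [kinetic_trace()], times in minutes) and `features` (data frame with
#'   `cluster`, `lag_min`, `area_um2`, `receptor_intensity`).
#' @export
gen_actin_timecourse <- function(n_clusters = 50L, lag_range = c(6, 15),
                                 rise_tau = 2, frame_interval = 3,
                                 duration = 30, plateau = 1, baseline = 0.05,
                                 noise_sd = 0.01, seed = 1L) {
  if (length(lag_range) != 2 || lag_range[1] > lag_range[2])
    stop("lag_range must be an increasing pair")
  if (lag_range[1] < 0 || lag_range[2] > duration)
    stop("lag_range must lie within [0, duration]")
  if (rise_tau <= 0) stop("rise_tau must be positive")
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = frame_interval)
  lags <- stats::runif(n_clusters, lag_range[1], lag_range[2])
  area <- stats::runif(n_clusters, 0.5, 5)
  receptor <- area * stats::runif(n_clusters, 0.8, 1.2) * 100
  traces <- lapply(seq_len(n_clusters), function(i) {
    v <- baseline + plateau * (1 - exp(-pmax(times - lags[i], 0) / rise_tau)) *
      (times > lags[i])
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    kinetic_trace(times, v, n_prebleach = 0L, time_unit = "min")
  })
  structure(list(traces = traces,
                 features = data.frame(cluster = seq_len(n_clusters),
                                       lag_min = lags, area_um2 = area,
                                       receptor_intensity = receptor)),
            class = "actin_dataset")
}
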