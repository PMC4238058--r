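#' Fractional intensity in clusters
#'
#' First order parameter of the two-dimensional phase transition: the fraction
#' of total image fluorescence residing in thresholded cluster regions
#' (integrated intensity over cluster pixels divided by integrated intensity
#' over the whole image).
#'
#' @param image a [raster_image()] or matrix.
#' @param clusters a `labeled_clusters` object for the same image.
#' @return A number in `[0, 1]`.
#' @export
fractional_intensity <- function(image, clusters) {
  v <- as_raster(image)$values
  if (!identical(dim(v), dim(clusters$label_map)))
    stop("image and label map shapes differ")
  tot <- sum(v)
  if (tot == 0) stop("zero total intensity")
  sum(v[clusters$label_map > 0L]) / tot
}

#' Signal variance across the bilayer
#'
#' Second order parameter: the population variance of pixel intensities, which
#' rises sharply when bright clustered regions appear. Compute it on
#' flat-field-corrected images so that illumination gradients do not
#' masquerade as clustering; the dimensionless `cv2()` is reported alongside
#' in [titration_statistics()] for the same reason.
#'
#' @param image a [raster_image()] or matrix.
#' @return Population variance (counts^2).
#' @export
signal_variance <- function(image) {
  v <- as_raster(image)$values
  mean((v - mean(v))^2)
}

#' Squared coefficient of variation
#'
#' `var / mean^2` of pixel intensities; a scale-free companion to
#' [signal_variance()].
#'
#' @param image a [raster_image()] or matrix.
#' @return Dimensionless CV^2.
#' @export
cv2 <- function(image) {
  v <- as_raster(image)$values
  signal_variance(image) / mean(v)^2
}

#' Cluster enrichment ratio
#'
#' Mean intensity over cluster pixels divided by mean intensity over
#' non-cluster pixels, the fold-enrichment of protein density within the
#' phase-separated regions. Also returns per-cluster ratios.
#'
#' @param image a [raster_image()] or matrix.
#' @param clusters a `labeled_clusters` object; both cluster and background
#'   pixels must exist.
#' @return A list with `ratio`, `per_cluster` (data frame `id`, `ratio`) and
#'   `background_mean`.
#' @export
enrichment_ratio <- function(image, clusters) {
  v <- as_raster(image)$values
  lab <- clusters$label_map
  if (!identical(dim(v), dim(lab))) stop("image and label map shapes differ")
  fg <- lab > 0L
  if (!any(fg)) stop("empty cluster set")
  if (all(fg)) stop("empty background")
  bg_mean <- mean(v[!fg])
  per <- clusters$clusters$mean_intensity / bg_mean
  list(ratio = mean(v[fg]) / bg_mean,
       per_cluster = data.frame(id = clusters$clusters$id, ratio = per),
       background_mean = bg_mean)
}

#' Intensity profile along a line segment
#'
#' Bilinear interpolation of the image along the segment from `from` to `to`
#' (0-based pixel coordinates, `c(x, y)`), the classic line-scan used to
#' visualize cluster enrichment.
#'
#' @param image a [raster_image()] or matrix.
#' @param from,to segment endpoints, `c(x, y)` in 0-based pixel coordinates.
#' @param n number of samples along the segment.
#' @return Data frame with `distance_um` and `intensity`.
#' @export
line_scan <- function(image, from, to, n = 256L) {
  img <- as_raster(image)
  v <- img$values
  s <- seq(0, 1, length.out = n)
  x <- from[1] + s * (to[1] - from[1])
  y <- from[2] + s * (to[2] - from[2])
  # bilinear interpolation; matrix row = y + 1, col = x + 1
  x0 <- pmin(pmax(floor(x), 0), ncol(v) - 1); x1 <- pmin(x0 + 1, ncol(v) - 1)
  y0 <- pmin(pmax(floor(y), 0), nrow(v) - 1); y1 <- pmin(y0 + 1, nrow(v) - 1)
  fx <- x - x0; fy <- y - y0
  at <- function(r, c) v[cbind(r + 1, c + 1)]
  val <- (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x1) +
    (1 - fx) * fy * at(y1, x0) + fx * fy * at(y1, x1)
  data.frame(distance_um = s * sqrt(sum((to - from)^2)) * img$pixel_size,
             intensity = val)
}

# Coerce supported titration inputs to a list of (concentration, raster_image).
as_titration_list <- function(images) {
  if (inherits(images, "titration_scenes"))
    return(lapply(unclass(images), function(e)
      list(concentration = e$concentration, image = e$scene$image)))
  lapply(images, function(e) {
    if (is.null(e$concentration) || is.null(e$image))
      stop("each entry must have elements 'concentration' and 'image'")
    list(concentration = e$concentration, image = as_raster(e$image))
  })
}

#' Order parameters along a titration series
#'
#' For each concentration, thresholds and segments the image and records both
#' order parameters: fractional intensity in clusters and signal variance
#' (plus CV^2 and the cluster count). Degenerate images on which no threshold
#' exists (e.g. constant, cluster-free fields) are recorded with fractional
#' intensity 0. When several image tiles share a concentration their
#' statistics are averaged and the standard deviation propagated.
#'
#' @param images a `titration_scenes` object from [gen_titration()], or a list
#'   of `list(concentration =, image =)` entries sorted by concentration.
#' Images are assumed flat-field corrected (as in the experimental protocol);
#' histogram thresholds on uncorrected, vignetted fields reflect the
#' illumination profile rather than clustering.
#'
#' A cluster-free image has no bimodal structure, so a histogram threshold
#' merely splits the noise distribution and the "clusters" it produces are
#' statistically indistinguishable from background. Such images are detected
#' by requiring a minimum intensity contrast: if the mean intensity of the
#' thresholded regions is less than `min_contrast` times the background mean,
#' the image is recorded as cluster-free (fractional intensity 0). Genuine
#' clusters are several-fold enriched, while noise partitions sit within a few
#' percent of 1.
#'
#' @param method threshold method passed to [compute_threshold()].
#' @param bins histogram bins for thresholding.
#' @param min_area_px minimum cluster area for [segment_clusters()].
#' @param min_contrast minimum cluster/background mean-intensity ratio for an
#'   image to count as clustered.
#' @return A data frame of class `titration_curve` with columns
#'   `concentration`, `fractional_intensity`, `variance`, `cv2`, `n_clusters`,
#'   `n_tiles`, `sd_fractional_intensity`.
#' @export
titration_statistics <- function(images, method = "triangle", bins = 256L,
                                 min_area_px = 4L, min_contrast = 1.5) {
  entries <- as_titration_list(images)
  conc <- vapply(entries, function(e) e$concentration, numeric(1))
  if (length(unique(conc)) < 4) stop("at least 4 concentrations are required")
  if (is.unsorted(conc)) stop("concentrations must be sorted increasingly")
  fi <- va <- cv <- nc <- numeric(length(entries))
  for (i in seq_along(entries)) {
    img <- entries[[i]]$image
    thr <- tryCatch(compute_threshold(img, method = method, bins = bins),
                    error = function(e) NA_real_)
    if (is.na(thr)) {
      fi[i] <- 0; nc[i] <- 0
    } else {
      cl <- segment_clusters(img, thr, min_area_px = min_area_px)
      fg <- cl$label_map > 0L
      contrast <- if (!any(fg) || all(fg)) 1
                  else mean(img$values[fg]) / mean(img$values[!fg])
      if (nrow(cl$clusters) == 0 || contrast < min_contrast) {
        fi[i] <- 0; nc[i] <- 0
      } else {
        fi[i] <- fractional_intensity(img, cl)
        nc[i] <- nrow(cl$clusters)
      }
    }
    va[i] <- signal_variance(img)
    cv[i] <- cv2(img)
  }
  agg <- function(x, f) as.vector(tapply(x, conc, f))
  out <- data.frame(concentration = sort(unique(conc)),
                    fractional_intensity = agg(fi, mean),
                    variance = agg(va, mean),
                    cv2 = agg(cv, mean),
                    n_clusters = agg(nc, mean),
                    n_tiles = as.vector(table(conc)),
                    sd_fractional_intensity = agg(fi, stats::sd))
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Estimate the clustering (critical) concentration
#'
#' Finds the concentration at which an order parameter begins increasing, the
#' operational definition of the two-dimensional phase boundary. The primary
#' `"hockey_stick"` method least-squares fits a flat baseline joined to a
#' rising linear segment, scanning the breakpoint over the interior grid
#' points; a breakpoint is reported as detected only if the post-break slope
#' is positive at `p < alpha` (one-sided t-test) and the two-segment model
#' beats the flat model by an F-test at `alpha`. The secondary
#' `"baseline_3sd"` method returns the first concentration whose statistic
#' exceeds the mean + 3 SD of the first `k_baseline` points.
#'
#' @param curve a `titration_curve` from [titration_statistics()].
#' @param statistic which order parameter to analyze.
#' @param method `"hockey_stick"` or `"baseline_3sd"`.
#' @param alpha significance level for the hockey-stick tests.
#' @param k_baseline number of initial points defining the baseline for
#'   `"baseline_3sd"`.
#' @return A list of class `breakpoint_estimate`: `concentration` (NA when not
#'   detected), `detected`, `baseline_level`, `post_slope`, `sse`, `p_slope`,
#'   `p_F`, `method`, `statistic`.
#' @export
clustering_concentration <- function(curve,
                                     statistic = c("fractional_intensity",
                                                   "variance", "cv2"),
                                     method = c("hockey_stick", "baseline_3sd"),
                                     alpha = 0.05, k_baseline = 3L) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  x <- curve$concentration
  y <- curve[[statistic]]
  n <- length(x)
  if (n < 4) stop("at least 4 titration points are required")
  if (method == "baseline_3sd") {
    base <- y[seq_len(min(k_baseline, n - 1))]
    lim <- mean(base) + 3 * stats::sd(base)
    hit <- which(y > lim)
    hit <- hit[hit > k_baseline]
    detected <- length(hit) > 0
    return(structure(list(concentration = if (detected) x[hit[1]] else NA_real_,
                          detected = detected, baseline_level = mean(base),
                          post_slope = NA_real_, sse = NA_real_,
                          p_slope = NA_real_, p_F = NA_real_,
                          method = method, statistic = statistic),
                     class = "breakpoint_estimate"))
  }
  grid <- x[2:(n - 1)]
  best <- NULL
  for (cb in grid) {
    z <- pmax(x - cb, 0)
    f <- stats::lm(y ~ z)
    sse <- sum(stats::residuals(f)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(cb = cb, fit = f, sse = sse)
  }
  co <- suppressWarnings(summary(best$fit)$coefficients)
  slope <- co["z", "Estimate"]
  # one-sided: slope > 0
  p_slope <- if (best$sse <= .Machine$double.eps * sum(y^2)) {
    if (slope > 0) 0 else 1
  } else stats::pt(co["z", "t value"], df = n - 2, lower.tail = FALSE)
  sse0 <- sum((y - mean(y))^2)
  df2 <- n - 3
  if (best$sse <= .Machine$double.eps * max(sse0, 1)) {
    p_F <- 0
  } else {
    Fstat <- ((sse0 - best$sse) / 2) / (best$sse / df2)
    p_F <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  }
  detected <- slope > 0 && p_slope < alpha && p_F < alpha
  structure(list(concentration = if (detected) best$cb else NA_real_,
                 breakpoint = best$cb,
                 detected = detected,
                 baseline_level = unname(co["(Intercept)", "Estimate"]),
                 post_slope = unname(slope), sse = best$sse,
                 p_slope = unname(p_slope), p_F = p_F,
                 method = method, statistic = statistic),
            class = "breakpoint_estimate")
}

#' @export
print.breakpoint_estimate <- function(x, ...) {
  if (x$detected)
    cat(sprintf("clustering concentration: %.4g (method %s, statistic %s)\n",
                x$concentration, x$method, x$statistic))
  else
    cat(sprintf("no clustering onset detected (method %s, statistic %s)\n",
                x$method, x$statistic))
  invisible(x)
}
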