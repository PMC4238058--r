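# Histogram of intensities over [min, max] with a fixed number of bins.
# Returns counts, bin breaks and midpoints.
intensity_histogram <- function(x, bins) {
  mn <- min(x); mx <- max(x)
  breaks <- seq(mn, mx, length.out = bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  list(counts = tabulate(bin, nbins = bins), breaks = breaks,
       mids = (breaks[-1] + breaks[-(bins + 1)]) / 2)
}

# Triangle threshold on a histogram: anchor a line at the global peak and at
# the farthest nonzero bin on the longer tail side, and return the bin with
# maximum perpendicular distance to that line (ties broken toward higher
# intensity, since clusters are bright). Returns the selected bin index.
triangle_bin <- function(counts) {
  h <- as.numeric(counts)
  nz <- which(h > 0)
  if (length(nz) < 2) stop("histogram is degenerate; no threshold exists")
  lo <- nz[1]; hi <- nz[length(nz)]
  peak <- which.max(h)
  far <- if ((hi - peak) >= (peak - lo)) hi else lo
  if (far == peak) stop("histogram is degenerate; no threshold exists")
  i <- if (far > peak) peak:far else far:peak
  # perpendicular distance (up to a common factor) from (i, h[i]) to the line
  # through (peak, h[peak]) and (far, h[far])
  d <- abs((h[peak] - h[far]) * i - (peak - far) * h[i] +
             peak * h[far] - far * h[peak])
  cand <- i[d == max(d)]
  cand[length(cand)]
}

# Maximum-entropy (Kapur) threshold: the split s maximizing the sum of Shannon
# entropies of the below (bins 1..s) and above (bins s+1..B) partitions.
# Ties broken toward higher intensity. Returns the split bin index s.
max_entropy_bin <- function(counts) {
  h <- as.numeric(counts)
  if (sum(h > 0) < 2) stop("histogram is degenerate; no threshold exists")
  p <- h / sum(h)
  P <- cumsum(p)
  hterm <- ifelse(p > 0, -p * log(p), 0)
  cumH <- cumsum(hterm)
  B <- length(p)
  s <- seq_len(B - 1)
  ok <- P[s] > 0 & P[s] < 1
  crit <- rep(-Inf, B - 1)
  Ps <- P[s][ok]
  crit[ok] <- cumH[s][ok] / Ps + log(Ps) +
    (cumH[B] - cumH[s][ok]) / (1 - Ps) + log(1 - Ps)
  cand <- which(crit == max(crit))
  cand[length(cand)]
}

#' Histogram threshold of a bilayer image
#'
#' Computes the intensity threshold separating clustered (bright) regions from
#' the surrounding bilayer using one of three methods. `"triangle"` builds a
#' `bins`-bin histogram, draws a line from the histogram peak to the farthest
#' nonzero tail bin, and returns the intensity at the bin maximizing the
#' perpendicular distance to that line. `"max_entropy"` returns the split
#' maximizing the summed Shannon entropies of the two intensity partitions.
#' `"sd_iterative"` iterates `t <- mean(I[I < t]) + 3 sd(I[I < t])` from
#' `t0 = mean(I) + 3 sd(I)` until the threshold changes by less than 0.1% (or
#' 100 iterations), the "three standard deviations above the non-clustered
#' mean" rule. Histograms are computed on the raw intensities (no 8-bit
#' conversion).
#'
#' @param image a [raster_image()] or matrix.
#' @param method `"triangle"`, `"max_entropy"`, or `"sd_iterative"`.
#' @param bins number of histogram bins (>= 8); 256 by default.
#' @return The threshold in intensity units; pixels strictly above it belong
#'   to clusters.
#' @examples
#' v <- matrix(c(rep(10, 99), 100), 10, 10)
#' compute_threshold(v, "triangle")
#' @export
compute_threshold <- function(image,
                              method = c("triangle", "max_entropy",
                                         "sd_iterative"),
                              bins = 256L) {
  method <- match.arg(method)
  x <- as_raster(image)$values
  if (bins < 8) stop("bins must be at least 8")
  if (method %in% c("triangle", "max_entropy")) {
    if (min(x) == max(x))
      stop("constant image: no threshold exists")
    hh <- intensity_histogram(x, bins)
    bin <- if (method == "triangle") triangle_bin(hh$counts)
           else max_entropy_bin(hh$counts)
    return(hh$breaks[bin + 1L])
  }
  # sd_iterative
  t <- mean(x) + 3 * stats::sd(x)
  for (it in seq_len(100L)) {
    below <- x[x < t]
    # a spread-less background makes the 3-SD update degenerate: keep the
    # current threshold
    if (length(below) < 2 || stats::sd(below) == 0) break
    t_new <- mean(below) + 3 * stats::sd(below)
    if (abs(t_new - t) < 0.001 * abs(t)) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t
}

# 8-connectivity connected-component labeling of a logical mask. Components
# are numbered consecutively 1..N in order of their smallest linear pixel
# index. Implemented as graph components over the pixel adjacency graph.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  inmask <- logical(nr * nc)
  inmask[idx] <- TRUE
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  edges <- vector("list", 4L)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(offs)) {
    nbr <- row + offs[[k]][1]; nbc <- col + offs[[k]][2]
    ok <- nbr >= 1L & nbr <= nr & nbc <= nc
    nb <- (nbc - 1L) * nr + nbr
    ok[ok] <- inmask[nb[ok]]
    edges[[k]] <- cbind(idx[ok], nb[ok])
  }
  e <- do.call(rbind, edges)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e) > 0)
    g <- igraph::add_edges(g, rbind(vid[e[, 1]], vid[e[, 2]]))
  memb <- igraph::components(g)$membership
  # renumber so labels appear in order of first pixel occurrence
  first <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first]] <- seq_len(sum(first))
  lab[idx] <- remap[memb]
  lab
}

#' Segment clusters above a threshold
#'
#' Thresholds the image (`pixel > threshold`), labels connected components at
#' 8-connectivity, discards components smaller than `min_area_px`, and
#' measures each remaining cluster. Alternatively a precomputed logical
#' `mask` (e.g. a generator ground-truth mask) can be supplied in place of
#' thresholding.
#'
#' @param image a [raster_image()] or matrix (intensities used for the
#'   per-cluster measurements).
#' @param threshold intensity threshold, e.g. from [compute_threshold()].
#' @param min_area_px minimum cluster area in pixels; smaller components are
#'   treated as noise and dropped.
#' @param mask optional logical matrix overriding the thresholding step.
#' @return An object of class `labeled_clusters`: list with `label_map`
#'   (integer matrix, 0 = background, labels consecutive 1..N), `clusters`
#'   (data frame with `id`, `area_px`, `area_um2`, `integrated_intensity`,
#'   `mean_intensity`, `centroid_x`, `centroid_y` in 0-based pixel
#'   coordinates, `touches_image_edge`), `pixel_size` and `threshold`.
#' @export
segment_clusters <- function(image, threshold = NULL, min_area_px = 4L,
                             mask = NULL) {
  img <- as_raster(image)
  v <- img$values
  if (is.null(mask)) {
    if (is.null(threshold) || !is.finite(threshold))
      stop("a finite threshold (or a mask) is required")
    mask <- v > threshold
  } else {
    if (!identical(dim(mask), dim(v))) stop("mask shape does not match image")
    mask <- mask > 0
  }
  lab <- label_components(mask)
  nlab <- max(lab)
  empty <- data.frame(id = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), integrated_intensity = numeric(0),
                      mean_intensity = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), touches_image_edge = logical(0))
  if (nlab > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = nlab)
    keep <- which(areas >= min_area_px)
    remap <- integer(nlab)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    nlab <- length(keep)
  }
  if (nlab == 0L) {
    lab[] <- 0L
    return(structure(list(label_map = lab, clusters = empty,
                          pixel_size = img$pixel_size,
                          threshold = if (is.null(threshold)) NA_real_ else threshold),
                     class = "labeled_clusters"))
  }
  nr <- nrow(v); nc <- ncol(v)
  idx <- which(lab > 0L)
  l <- lab[idx]
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  area <- tabulate(l, nbins = nlab)
  integ <- as.vector(rowsum(v[idx], l))
  cx <- as.vector(rowsum(as.numeric(col - 1L), l)) / area
  cy <- as.vector(rowsum(as.numeric(row - 1L), l)) / area
  on_edge <- as.vector(rowsum(as.numeric(row == 1L | row == nr |
                                           col == 1L | col == nc), l)) > 0
  clusters <- data.frame(id = seq_len(nlab), area_px = area,
                         area_um2 = area * img$pixel_size^2,
                         integrated_intensity = integ,
                         mean_intensity = integ / area,
                         centroid_x = cx, centroid_y = cy,
                         touches_image_edge = on_edge)
  structure(list(label_map = lab, clusters = clusters,
                 pixel_size = img$pixel_size,
                 threshold = if (is.null(threshold)) NA_real_ else threshold),
            class = "labeled_clusters")
}

#' @export
print.labeled_clusters <- function(x, ...) {
  cat(sprintf("labeled_clusters: %d clusters (threshold %.4g)\n",
              nrow(x$clusters), x$threshold))
  if (nrow(x$clusters) > 0)
    cat(sprintf("  area %.3g-%.3g um^2, %d touching the image edge\n",
                min(x$clusters$area_um2), max(x$clusters$area_um2),
                sum(x$clusters$touches_image_edge)))
  invisible(x)
}
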