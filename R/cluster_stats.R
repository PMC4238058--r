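#' Cluster size distribution
#'
#' Bins the areas of non-edge clusters (those not touching the image border)
#' on a linear size axis. The default bin width follows the Freedman-Diaconis
#' rule, floored at one pixel area.
#'
#' @param clusters a `labeled_clusters` object, or a numeric vector of cluster
#'   areas in um^2.
#' @param bin_width bin width in um^2; `NULL` for Freedman-Diaconis.
#' @param start left edge of the first bin (um^2).
#' @param pixel_area floor on the automatic bin width (um^2); taken from the
#'   `labeled_clusters` object when available.
#' @return A list of class `size_distribution`: `bin_edges`, `mids`, `counts`,
#'   `bin_width`, `n_excluded_edge_clusters`.
#' @export
size_distribution <- function(clusters, bin_width = NULL, start = 0,
                              pixel_area = NULL) {
  if (inherits(clusters, "labeled_clusters")) {
    cl <- clusters$clusters
    areas <- cl$area_um2[!cl$touches_image_edge]
    n_excl <- sum(cl$touches_image_edge)
    if (is.null(pixel_area)) pixel_area <- clusters$pixel_size^2
  } else {
    areas <- as.numeric(clusters)
    n_excl <- 0L
    if (is.null(pixel_area)) pixel_area <- 0
  }
  if (length(areas) == 0) stop("no non-edge clusters")
  if (is.null(bin_width)) {
    bin_width <- 2 * stats::IQR(areas) / length(areas)^(1 / 3)
    bin_width <- max(bin_width, pixel_area)
    if (bin_width <= 0) bin_width <- max(areas) / 10
  }
  nb <- max(1L, ceiling((max(areas) - start) / bin_width + 1e-9))
  edges <- start + bin_width * (0:nb)
  if (max(areas) >= edges[length(edges)]) edges <- c(edges, max(edges) + bin_width)
  bin <- findInterval(areas, edges, rightmost.closed = TRUE)
  if (any(bin < 1)) stop("areas below the first bin edge")
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, bin_width = bin_width,
                 n_excluded_edge_clusters = n_excl),
            class = "size_distribution")
}

#' Exponential versus power-law size model discrimination
#'
#' Fits straight lines to (size, log count) and (log size, log count) over the
#' occupied bins, the log-linear/log-log regression diagnostic for
#' distinguishing an exponential size law (stochastic nucleation and growth)
#' from a power law (coalescence-dominated growth). Both regressions weight
#' bins by their counts, the standard variance-stabilizing weighting for log
#' counts (`var(log N) ~ 1/N` for Poisson bins), so sparsely populated tail
#' bins do not dominate the fit. The model with higher r^2 by a margin of at
#' least 0.02 is preferred, otherwise the comparison is `"indeterminate"`.
#' Zero-count bins are excluded (log undefined). A direct nonlinear fit of
#' `N(s) = a exp(-s / sbar)` is included as a cross-check.
#'
#' @param dist a [size_distribution()].
#' @param margin minimum r^2 advantage required to prefer a model.
#' @return A list of class `size_model_comparison`: `exp_rate` (1/um^2),
#'   `exp_r2`, `power_exponent`, `power_r2`, `preferred`, `sbar`
#'   (`= 1/exp_rate`, um^2), `sbar_direct` from the nonlinear fit.
#' @export
fit_size_model <- function(dist, margin = 0.02) {
  occ <- which(dist$counts > 0)
  if (length(occ) < 4) stop("fewer than 4 occupied bins")
  x <- dist$mids[occ]
  y <- dist$counts[occ]
  fe <- stats::lm(log(y) ~ x, weights = y)
  fp <- stats::lm(log(y) ~ log(x), weights = y)
  exp_r2 <- suppressWarnings(summary(fe)$r.squared)
  power_r2 <- suppressWarnings(summary(fp)$r.squared)
  exp_rate <- -unname(stats::coef(fe)[2])
  preferred <- if (exp_r2 - power_r2 >= margin) "exponential"
               else if (power_r2 - exp_r2 >= margin) "power_law"
               else "indeterminate"
  sbar_direct <- tryCatch({
    f <- minpack.lm::nlsLM(y ~ a * exp(-x / sbar),
                           start = list(a = max(y),
                                        sbar = max(1 / max(exp_rate, 1e-12),
                                                   mean(x))))
    unname(stats::coef(f)[["sbar"]])
  }, error = function(e) NA_real_)
  structure(list(exp_rate = exp_rate, exp_r2 = exp_r2,
                 power_exponent = unname(stats::coef(fp)[2]),
                 power_r2 = power_r2, preferred = preferred,
                 sbar = 1 / exp_rate, sbar_direct = sbar_direct),
            class = "size_model_comparison")
}

#' Quadrat (box) counts of clusters with edge correction
#'
#' Divides the label map into a `grid[1] x grid[2]` array of boxes (remainder
#' pixels assigned to the last row/column) and counts clusters per box twice:
#' including clusters that intersect the box and excluding clusters not fully
#' inside it. A cluster spanning k boxes is counted in each of the k boxes'
#' "including" tallies; half the average per-box excess
#' (`including - excluding`) is subtracted from each including count to remove
#' this double counting.
#'
#' @param clusters a `labeled_clusters` object.
#' @param grid integer pair: boxes along rows and columns (default 5 x 5,
#'   i.e. 25 boxes).
#' @return A list of class `box_count_result`: `grid`,
#'   `counts_including_edges`, `counts_excluding_edges`, `avg_edge_clusters`,
#'   `corrected_counts` (all per box, row-major).
#' @export
box_counts <- function(clusters, grid = c(5L, 5L)) {
  lab <- clusters$label_map
  nr <- nrow(lab); nc <- ncol(lab)
  grid <- as.integer(grid)
  if (grid[1] > nr || grid[2] > nc) stop("grid larger than image")
  nbox <- grid[1] * grid[2]
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    z <- numeric(nbox)
    return(structure(list(grid = grid, counts_including_edges = z,
                          counts_excluding_edges = z, avg_edge_clusters = 0,
                          corrected_counts = z),
                     class = "box_count_result"))
  }
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  rbox <- pmin((row - 1L) %/% (nr %/% grid[1]) + 1L, grid[1])
  cbox <- pmin((col - 1L) %/% (nc %/% grid[2]) + 1L, grid[2])
  box <- (rbox - 1L) * grid[2] + cbox
  l <- lab[idx]
  key <- unique((as.numeric(l) - 1) * nbox + box)
  lu <- (key - 1) %/% nbox + 1
  bu <- as.integer((key - 1) %% nbox + 1)
  including <- tabulate(bu, nbins = nbox)
  span <- tabulate(lu, nbins = max(lu))
  inside <- span[lu] == 1L
  excluding <- tabulate(bu[inside], nbins = nbox)
  avg_edge <- mean(including - excluding)
  structure(list(grid = grid, counts_including_edges = including,
                 counts_excluding_edges = excluding,
                 avg_edge_clusters = avg_edge,
                 corrected_counts = including - avg_edge / 2),
            class = "box_count_result")
}

#' Gaussian fit to corrected quadrat counts
#'
#' Pools corrected box counts across images, builds a relative-frequency
#' histogram on unit-width bins, and fits a Gaussian by least squares; a
#' Gaussian (i.e. spatially random, independently nucleated) distribution of
#' cluster counts is the signature of stochastic cluster assembly. A
#' Shapiro-Wilk normality p-value is reported as a cross-check.
#'
#' @param results a `box_count_result` or list of them.
#' @return A list with `mean`, `sd`, `r2`, `p_normality`, `n_boxes`.
#' @export
fit_gaussian_counts <- function(results) {
  if (inherits(results, "box_count_result")) results <- list(results)
  counts <- unlist(lapply(results, function(r) r$corrected_counts))
  if (length(counts) < 20) stop("at least 20 boxes are required")
  if (stats::sd(counts) == 0) stop("zero-variance counts: Gaussian fit degenerate")
  br <- seq(floor(min(counts)) - 0.5, ceiling(max(counts)) + 0.5, by = 1)
  h <- graphics::hist(counts, breaks = br, plot = FALSE)
  x <- h$mids
  freq <- h$counts / sum(h$counts)
  fit <- minpack.lm::nlsLM(freq ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                           start = list(a = max(freq), mu = mean(counts),
                                        s = stats::sd(counts)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((freq - mean(freq))^2)
  sw <- stats::shapiro.test(if (length(counts) > 5000)
    sample(counts, 5000) else counts)
  co <- stats::coef(fit)
  list(mean = unname(co[["mu"]]), sd = abs(unname(co[["s"]])),
       r2 = 1 - rss / tss, p_normality = sw$p.value, n_boxes = length(counts))
}
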