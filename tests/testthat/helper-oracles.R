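# Independent brute-force oracles, deliberately written as plain loops over
# the textbook definitions so they share no code with the implementation.

# Triangle threshold: explicit point-to-line distance for every bin between
# the histogram peak and the farthest nonzero bin on the longer tail side;
# ties toward higher intensity.
brute_triangle <- function(h) {
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  peak <- which.max(h)
  far <- if ((hi - peak) >= (peak - lo)) hi else lo
  x1 <- peak; y1 <- h[peak]; x2 <- far; y2 <- h[far]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  best <- -1; best_bin <- NA_integer_
  rng <- if (far > peak) peak:far else far:peak
  for (b in rng) {
    d <- abs((y2 - y1) * b - (x2 - x1) * h[b] + x2 * y1 - y2 * x1) / len
    if (d > best || (d == best && b > best_bin)) {
      best <- d
      best_bin <- b
    }
  }
  best_bin
}

# Maximum-entropy threshold: for every split, recompute both partition
# entropies from scratch; ties toward higher intensity.
brute_max_entropy <- function(h) {
  p <- h / sum(h)
  B <- length(p)
  best <- -Inf; best_bin <- NA_integer_
  for (s in 1:(B - 1)) {
    Pb <- sum(p[1:s])
    if (Pb <= 0 || Pb >= 1) next
    Hb <- 0
    for (i in 1:s) if (p[i] > 0) Hb <- Hb - (p[i] / Pb) * log(p[i] / Pb)
    Hf <- 0
    for (i in (s + 1):B) if (p[i] > 0)
      Hf <- Hf - (p[i] / (1 - Pb)) * log(p[i] / (1 - Pb))
    if (Hb + Hf >= best) {
      best <- Hb + Hf
      best_bin <- s
    }
  }
  best_bin
}

# Grayscale erosion/dilation/opening by exhaustive neighborhood min/max over a
# disc footprint clipped at the image border.
brute_opening <- function(m, radius) {
  kern <- EBImage::makeBrush(2 * radius + 1, "disc")
  off <- which(kern > 0, arr.ind = TRUE) - (radius + 1)
  sweep1 <- function(m, f) {
    out <- matrix(NA_real_, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      rr <- i + off[, 1]; cc <- j + off[, 2]
      ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
      out[i, j] <- f(m[cbind(rr[ok], cc[ok])])
    }
    out
  }
  sweep1(sweep1(m, min), max)
}

# Random histogram with occasional zero bins, for threshold-oracle tests.
random_histogram <- function(bins) {
  h <- rpois(bins, lambda = sample(c(2, 20, 200), 1))
  h[sample(bins, size = floor(bins / 4))] <- 0
  if (sum(h > 0) < 2) h[c(1, bins)] <- c(5, 7)
  h
}
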