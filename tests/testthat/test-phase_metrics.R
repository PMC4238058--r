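make_clusters <- function(values, mask) {
  segment_clusters(raster_image(values, 0.16), mask = mask, min_area_px = 1)
}

test_that("fractional intensity is the exact intensity ratio", {
  v <- matrix(c(1, 1, 3, 5), 2, 2)
  mask <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  cl <- make_clusters(v, mask)
  expect_equal(fractional_intensity(v, cl), 0.8)
  # whole image and empty complement
  expect_equal(fractional_intensity(v, make_clusters(v, v > 0)), 1.0)
  expect_equal(fractional_intensity(v, make_clusters(v, v > 99)), 0.0)
  expect_error(fractional_intensity(matrix(0, 2, 2),
                                    make_clusters(v, mask)), "zero total")
  # complement fraction sums exactly to 1
  bg_frac <- sum(v[cl$label_map == 0]) / sum(v)
  expect_equal(fractional_intensity(v, cl) + bg_frac, 1.0)
})

test_that("signal variance is population variance, permutation invariant", {
  expect_equal(signal_variance(matrix(7, 3, 3)), 0)
  expect_equal(signal_variance(matrix(c(0, 2, 0, 2), 2, 2)), 1.0)
  set.seed(3)
  v <- matrix(runif(64), 8, 8)
  vp <- matrix(sample(v), 8, 8)
  expect_equal(signal_variance(v), signal_variance(vp))
  expect_equal(cv2(matrix(c(0, 2), 1, 2)), 1 / 1)
})

test_that("variance increases with enrichment at fixed morphology", {
  p1 <- scene_params(width = 96, height = 96, morphology = "nucleated",
                     enrichment = 1, vignette_strength = 0, seed = 7)
  p4 <- scene_params(width = 96, height = 96, morphology = "nucleated",
                     enrichment = 4, vignette_strength = 0, seed = 7)
  expect_gt(signal_variance(gen_bilayer_image(p4)$image),
            signal_variance(gen_bilayer_image(p1)$image))
})

test_that("enrichment ratio matches construction", {
  v <- matrix(10, 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[3:5, 3:5] <- TRUE
  expect_equal(enrichment_ratio(v, make_clusters(v, mask))$ratio, 1.0)
  v2 <- v; v2[mask] <- 40
  er <- enrichment_ratio(v2, make_clusters(v2, mask))
  expect_equal(er$ratio, 4.0)
  expect_equal(er$per_cluster$ratio, 4.0)
  # noisy generator scene: estimate close to truth
  p <- scene_params(width = 256, height = 256, morphology = "nucleated",
                    vignette_strength = 0, camera_offset = 0, noise_sd = 20,
                    enrichment = 4, seed = 19)
  sc <- gen_bilayer_image(p)
  cl <- make_clusters(sc$image$values, sc$mask)
  expect_lt(abs(enrichment_ratio(sc$image, cl)$ratio - 4), 0.1)
  expect_error(enrichment_ratio(v, make_clusters(v, matrix(FALSE, 8, 8))),
               "empty cluster")
})

test_that("line scans read back a known profile", {
  v <- matrix(rep(1:10, each = 10), 10, 10)  # intensity = column index
  ls <- line_scan(v, from = c(0, 5), to = c(9, 5), n = 10)
  expect_equal(ls$intensity, 1:10)
  expect_equal(max(ls$distance_um), 9 * 0.16)
})

test_that("titration statistics handle null and clustered series", {
  # all cluster-free: flat curve at 0
  mk <- function(conc, seed) {
    p <- scene_params(width = 64, height = 64, morphology = "none",
                      vignette_strength = 0, seed = seed)
    list(concentration = conc, image = gen_bilayer_image(p)$image)
  }
  entries <- Map(mk, c(10, 20, 40, 80, 160), 1:5)
  cu <- titration_statistics(entries)
  expect_true(all(cu$fractional_intensity == 0))
  bp <- clustering_concentration(cu, "fractional_intensity")
  expect_false(bp$detected)
  expect_error(titration_statistics(entries[c(2, 1, 3, 4, 5)]), "sorted")
  expect_error(titration_statistics(entries[1:3]), "at least 4")
})

test_that("both order parameters rise at the generator's onset", {
  conc <- round(exp(seq(log(25), log(1000), length.out = 12)), 1)
  sc <- scene_params(width = 192, height = 192, vignette_strength = 0,
                     seed = 301)
  ts <- gen_titration(titration_params(conc, scene = sc))
  cu <- titration_statistics(ts)
  below <- cu$concentration <= 200
  expect_true(all(cu$fractional_intensity[below] == 0))
  expect_true(all(cu$fractional_intensity[!below] > 0))
  expect_gt(min(cu$variance[!below]), 10 * max(cu$variance[below]))
  bp_fi <- clustering_concentration(cu, "fractional_intensity")
  bp_var <- clustering_concentration(cu, "variance")
  expect_true(bp_fi$detected && bp_var$detected)
  # the two order parameters locate the onset coincidently (within one step)
  expect_lt(abs(bp_fi$concentration - bp_var$concentration), 80)
})

test_that("hockey-stick breakpoint is exact on a noiseless corner", {
  x <- c(50, 100, 150, 200, 250, 300, 400)
  y <- pmax(x - 200, 0) * 0.002 + 0.05
  bp <- clustering_concentration(
    structure(data.frame(concentration = x, fractional_intensity = y,
                         variance = y, cv2 = y),
              class = c("titration_curve", "data.frame")),
    "fractional_intensity")
  expect_true(bp$detected)
  expect_equal(bp$concentration, 200)
  expect_equal(bp$p_F, 0)
})

test_that("flat noisy curves yield no detection at the stated level", {
  set.seed(77)
  x <- seq(25, 1000, length.out = 10)
  hits <- 0
  for (i in 1:40) {
    y <- rnorm(10, 0.01, 0.002)
    bp <- clustering_concentration(
      structure(data.frame(concentration = x, fractional_intensity = y,
                           variance = y, cv2 = y),
                class = c("titration_curve", "data.frame")),
      "fractional_intensity")
    hits <- hits + bp$detected
  }
  expect_lt(hits / 40, 0.15)  # ~alpha-level false positives
})

test_that("baseline_3sd locates the first super-baseline point", {
  x <- c(25, 50, 100, 200, 400, 800)
  y <- c(0.010, 0.011, 0.009, 0.010, 0.3, 0.5)
  cu <- structure(data.frame(concentration = x, fractional_intensity = y,
                             variance = y, cv2 = y),
                  class = c("titration_curve", "data.frame"))
  bp <- clustering_concentration(cu, "fractional_intensity",
                                 method = "baseline_3sd")
  expect_true(bp$detected)
  expect_equal(bp$concentration, 400)
})

test_that("fractional intensity is monotone in the clustered fraction", {
  fis <- vapply(c(0.05, 0.15, 0.3), function(cf) {
    p <- scene_params(width = 128, height = 128, morphology = "spinodal",
                      clustered_fraction = cf, vignette_strength = 0,
                      noise_sd = 0, seed = 41)
    sc <- gen_bilayer_image(p)
    cl <- segment_clusters(sc$image, mask = sc$mask)
    fractional_intensity(sc$image, cl)
  }, numeric(1))
  expect_true(all(diff(fis) > 0))
})
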