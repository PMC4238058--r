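test_that("generators are seed-deterministic", {
  p <- scene_params(width = 96, height = 96, morphology = "nucleated", seed = 42)
  a <- gen_bilayer_image(p)
  b <- gen_bilayer_image(p)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$mask, b$mask)
  f <- frap_gen_params(c(5, 50), c(0.4, 0.6), seed = 9)
  expect_identical(gen_frap_trace(f)$values, gen_frap_trace(f)$values)
  expect_identical(gen_calibration(seed = 3)$dye, gen_calibration(seed = 3)$dye)
  p2 <- scene_params(width = 96, height = 96, morphology = "nucleated", seed = 43)
  expect_false(identical(gen_bilayer_image(p2)$image$values, a$image$values))
})

test_that("noiseless homogeneous scene is exactly constant", {
  p <- scene_params(width = 32, height = 32, morphology = "none", noise_sd = 0,
                    vignette_strength = 0, mean_intensity = 800,
                    camera_offset = 50)
  sc <- gen_bilayer_image(p)
  expect_true(all(sc$image$values == 850))
  expect_false(any(sc$mask))
})

test_that("noiseless nucleated scene has exactly the requested enrichment", {
  p <- scene_params(width = 128, height = 128, morphology = "nucleated",
                    noise_sd = 0, vignette_strength = 0, camera_offset = 0,
                    enrichment = 4, seed = 5)
  sc <- gen_bilayer_image(p)
  v <- sc$image$values
  expect_equal(mean(v[sc$mask]) / mean(v[!sc$mask]), 4.0)
})

test_that("per-image cluster counts follow the Poisson placement law", {
  # oracle: direct Poisson sampling at the same intensity
  p <- scene_params(width = 128, height = 128, pixel_size = 0.16,
                    morphology = "nucleated", cluster_density = 0.05,
                    noise_sd = 0, seed = 1)
  field_um2 <- 128^2 * 0.16^2
  lambda <- 0.05 * field_um2
  counts <- vapply(1:93, function(i) {
    p$seed <- 1000L + i
    nrow(gen_bilayer_image(p)$clusters)
  }, numeric(1))
  set.seed(7)
  oracle <- rpois(93, lambda)
  # means agree within combined standard errors
  se <- sqrt(lambda / 93) * 2
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_lt(abs(mean(counts) - mean(oracle)), 4 * se)
})

test_that("nucleated ground-truth areas converge to the exponential mean", {
  p <- scene_params(width = 512, height = 512, morphology = "nucleated",
                    cluster_density = 0.1, mean_cluster_area = 0.5,
                    noise_sd = 0, seed = 11)
  areas <- numeric(0)
  i <- 0L
  while (length(areas) < 5000) {
    i <- i + 1L
    p$seed <- 100L + i
    areas <- c(areas, gen_bilayer_image(p)$clusters$area_um2)
  }
  expect_gt(length(areas), 5000)
  expect_lt(abs(mean(areas) - 0.5) / 0.5, 0.05)
})

test_that("spinodal mask area fraction matches the requested fraction", {
  for (cf in c(0.15, 0.3, 0.5)) {
    p <- scene_params(width = 512, height = 512, morphology = "spinodal",
                      clustered_fraction = cf, noise_sd = 0, seed = 21)
    sc <- gen_bilayer_image(p)
    expect_lt(abs(mean(sc$mask) - cf), 0.02)
  }
  expect_error(gen_bilayer_image(scene_params(morphology = "spinodal",
                                              clustered_fraction = 1)),
               "spinodal")
})

test_that("scene parameter validation rejects bad inputs", {
  expect_error(scene_params(width = 0), "positive")
  expect_error(scene_params(mean_intensity = 0), "positive")
  expect_error(scene_params(noise_sd = -1), "non-negative")
  expect_error(scene_params(enrichment = 0.5), ">= 1")
  expect_error(scene_params(clustered_fraction = 1.2), "\\[0, 1\\]")
})

test_that("titration ground truth follows the stated onset law", {
  conc <- c(25, 50, 100, 150, 400, 800)
  tp <- titration_params(conc, critical_concentration = 200, rise_width = 300,
                         max_clustered_fraction = 0.3,
                         scene = scene_params(width = 48, height = 48))
  # closed form at c = c* + rise_width
  expect_equal(clustered_area_fraction(500, tp), 0.3 * (1 - exp(-1)))
  expect_equal(clustered_area_fraction(c(25, 200), tp), c(0, 0))
  ts <- gen_titration(tp)
  morphs <- vapply(ts, function(e) e$scene$params$morphology, character(1))
  expect_identical(morphs, c("none", "none", "none", "none",
                             "nucleated", "nucleated"))
  expect_equal(attr(ts, "truth")$critical_concentration, 200)
  expect_error(titration_params(c(100, 100, 300)), "strictly increasing")
  expect_error(titration_params(numeric(0)), "empty")
})

test_that("FRAP generator matches its closed form", {
  # no bleach: constant 1 before acquisition bleaching
  p0 <- frap_gen_params(10, 1, bleach_depth = 0, noise_sd = 0)
  expect_true(all(gen_frap_trace(p0)$values == 1))
  # single tau, mobile 1: f(tau) - f(0) = bleach_depth * (1 - exp(-1))
  p1 <- frap_gen_params(20, 1, bleach_depth = 0.6, mobile_fraction = 1,
                        frame_interval = 1, duration = 100, noise_sd = 0)
  tr <- gen_frap_trace(p1)
  post <- (tr$n_prebleach + 1):length(tr$times)
  s <- tr$times[post] - tr$times[post][1]
  f <- tr$values[post]
  expect_equal(f[s == 20] - f[s == 0], 0.6 * (1 - exp(-1)))
  # two-component clustered-receptor parameters: pointwise closed form
  p2 <- frap_gen_params(c(86, 526), c(0.76, 0.24), bleach_depth = 0.8,
                        frame_interval = 2, duration = 1000, noise_sd = 0)
  tr2 <- gen_frap_trace(p2)
  post2 <- (tr2$n_prebleach + 1):length(tr2$times)
  s2 <- tr2$times[post2] - tr2$times[post2][1]
  expected <- 0.2 + 0.8 * (0.76 * (1 - exp(-s2 / 86)) +
                             0.24 * (1 - exp(-s2 / 526)))
  expect_equal(tr2$values[post2], expected)
  # acquisition bleaching multiplies everything and is returned as reference
  p3 <- frap_gen_params(20, 1, bleach_depth = 0.5, acq_bleach_tau = 500,
                        noise_sd = 0)
  tr3 <- gen_frap_trace(p3)
  expect_equal(tr3$reference, exp(-tr3$times / 500))
  expect_equal(tr3$values[1:tr3$n_prebleach],
               exp(-tr3$times[1:tr3$n_prebleach] / 500))
  expect_error(frap_gen_params(c(5, 50), c(0.3, 0.4)), "sum to 1")
  expect_error(frap_gen_params(-2, 1), "positive")
})

test_that("calibration generator is exact at zero noise", {
  ds <- gen_calibration(dye_slope = 2, protein_slope = 4, noise_sd = 0)
  expect_equal(ds$protein$intensity, 4 * ds$protein$x)
  expect_equal(ds$truth$F, 2)
  expect_equal(gen_calibration(dye_slope = 3, protein_slope = 3,
                               noise_sd = 0)$truth$F, 1)
  expect_error(gen_calibration(n_points = 1), "at least 2")
  expect_error(gen_calibration(dye_slope = 0), "positive")
})

test_that("actin generator respects lag range and frame raster", {
  ds <- gen_actin_timecourse(n_clusters = 40, lag_range = c(6, 15),
                             frame_interval = 3, duration = 30, seed = 2)
  expect_true(all(ds$features$lag_min >= 6 & ds$features$lag_min <= 15))
  expect_equal(ds$traces[[1]]$times, seq(0, 30, by = 3))
  expect_error(gen_actin_timecourse(lag_range = c(6, 40), duration = 30),
               "within")
})
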