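test_that("FRAP normalization performs the stated quotient arithmetic", {
  # pre-bleach 100, background 10, constant reference 100, first post 40:
  # (40 - 10) / (100 - 10) = 1/3
  tr <- kinetic_trace(times = 0:5, values = c(100, 100, 40, 50, 60, 70),
                      n_prebleach = 2, reference = rep(100, 6),
                      background = 10)
  nt <- normalize_frap(tr)
  expect_equal(nt$values[1:2], c(1, 1))
  expect_equal(nt$values[3], (40 - 10) / (100 - 10))
  # identity: no bleach, no decay
  tr2 <- kinetic_trace(0:9, rep(55, 10), n_prebleach = 3)
  expect_true(all(normalize_frap(tr2)$values == 1))
  expect_error(normalize_frap(kinetic_trace(0:3, c(1, 0.5, 0.4, 0.6),
                                            n_prebleach = 1)), "pre-bleach")
  expect_error(normalize_frap(kinetic_trace(0:3, 1:4, n_prebleach = 2,
                                            reference = rep(0.5, 4),
                                            background = 1)),
               "exceed background")
})

test_that("normalization removes generator acquisition bleaching", {
  p <- frap_gen_params(c(5, 50), c(0.5, 0.5), bleach_depth = 0.7,
                       acq_bleach_tau = 400, frame_interval = 1,
                       duration = 200, noise_sd = 0)
  tr <- gen_frap_trace(p)
  nt <- normalize_frap(tr)
  post <- (nt$n_prebleach + 1):length(nt$times)
  s <- nt$times[post] - nt$times[post][1]
  expect_equal(nt$values[post], puncta:::frap_recovery_law(s, p),
               tolerance = 1e-12)
})

test_that("recovery fits recover noiseless parameters exactly", {
  # free receptor on the bilayer: tau = 1.3 s
  p1 <- frap_gen_params(1.3, 1, bleach_depth = 0.8, frame_interval = 0.1,
                        duration = 15, noise_sd = 0)
  f1 <- fit_recovery(normalize_frap(gen_frap_trace(p1)), 1)
  expect_equal(f1$taus, 1.3, tolerance = 1e-4)
  expect_equal(f1$plateau, 1, tolerance = 1e-6)
  # clustered receptor: two components, 86 s (76%) and 526 s (24%)
  p2 <- frap_gen_params(c(86, 526), c(0.76, 0.24), bleach_depth = 0.8,
                        frame_interval = 2, duration = 2000, noise_sd = 0)
  f2 <- fit_recovery(normalize_frap(gen_frap_trace(p2)), 2)
  expect_equal(f2$taus, c(86, 526), tolerance = 1e-4)
  expect_equal(f2$fractions, c(0.76, 0.24), tolerance = 1e-4)
  expect_error(fit_recovery(kinetic_trace(0:30, rep(1, 31), n_prebleach = 3)),
               "constant")
})

test_that("fits are invariant to time shift and intensity scaling", {
  p <- frap_gen_params(20, 1, bleach_depth = 0.6, frame_interval = 1,
                       duration = 150, noise_sd = 0.01, seed = 3)
  tr <- gen_frap_trace(p)
  f0 <- fit_recovery(normalize_frap(tr), 1)
  shifted <- kinetic_trace(tr$times + 500, tr$values,
                           n_prebleach = tr$n_prebleach)
  f1 <- fit_recovery(normalize_frap(shifted), 1)
  expect_equal(f1$taus, f0$taus)
  scaled <- kinetic_trace(tr$times, 370 * tr$values,
                          n_prebleach = tr$n_prebleach)
  f2 <- fit_recovery(normalize_frap(scaled), 1)
  expect_equal(f2$taus, f0$taus, tolerance = 1e-8)
})

test_that("nested-model F statistic matches the textbook formula", {
  mk <- function(ss, df) structure(list(ss_residual = ss, df = df),
                                   class = "exp_fit")
  ch <- select_model(mk(10, 100), mk(5, 98))
  expect_equal(ch$F_stat, 49.0)
  expect_equal(ch$df_num, 2)
  expect_equal(ch$p_value, pf(49, 2, 98, lower.tail = FALSE))
  expect_equal(ch$preferred, "double")
  # no improvement: F = 0, single preferred
  ch0 <- select_model(mk(5, 100), mk(5, 98))
  expect_equal(ch0$F_stat, 0)
  expect_equal(ch0$preferred, "single")
  # perfect richer fit
  chp <- select_model(mk(5, 100), mk(0, 98))
  expect_equal(chp$preferred, "double")
  expect_true(chp$perfect_fit)
  expect_error(select_model(mk(5, 98), mk(4, 100)), "nested")
})

test_that("model selection separates single from double truths", {
  # power: bi-exponential truth with tau ratio >= 10, both fractions >= 20%
  prefs <- vapply(1:20, function(i) {
    p <- frap_gen_params(c(4, 60), c(0.4, 0.6), bleach_depth = 0.8,
                         frame_interval = 0.5, duration = 300,
                         noise_sd = 0.01, seed = 400 + i)
    nt <- normalize_frap(gen_frap_trace(p))
    select_model(fit_recovery(nt, 1), fit_recovery(nt, 2))$preferred
  }, character(1))
  expect_gte(mean(prefs == "double"), 0.95)
  # type-I control on single-exponential truth (subset; full rate in the
  # acceptance suite)
  prefs1 <- vapply(1:30, function(i) {
    p <- frap_gen_params(31, 1, bleach_depth = 0.8, frame_interval = 1,
                         duration = 300, noise_sd = 0.01, seed = 800 + i)
    nt <- normalize_frap(gen_frap_trace(p))
    select_model(fit_recovery(nt, 1), fit_recovery(nt, 2))$preferred
  }, character(1))
  expect_lte(mean(prefs1 == "double"), 0.2)
})

test_that("parameter recovery stays inside the 95% CIs across seeds", {
  ok <- 0L
  n_seeds <- 30L
  for (i in seq_len(n_seeds)) {
    p <- frap_gen_params(c(5, 80), c(0.5, 0.5), bleach_depth = 0.8,
                         frame_interval = 0.5, duration = 400,
                         noise_sd = 0.01, seed = 1200 + i)
    f <- fit_recovery(normalize_frap(gen_frap_trace(p)), 2)
    ci <- f$ci95
    tau_ok <- all(sort(c(5, 80)) >= sort(ci[c("tau1", "tau2"), "lower"]) &
                    sort(c(5, 80)) <= sort(ci[c("tau1", "tau2"), "upper"]))
    ok <- ok + tau_ok
  }
  expect_gte(ok / n_seeds, 0.9)
})

test_that("dissociation decay fitting recovers its time constant", {
  d0 <- gen_dissociation_trace(tau = 2080, noise_sd = 0)
  f0 <- fit_decay(d0)
  expect_equal(f0$taus, 2080, tolerance = 1e-4)
  d1 <- gen_dissociation_trace(tau = 2080, noise_sd = 0.01, seed = 5)
  f1 <- fit_decay(d1)
  expect_lt(abs(f1$taus / 2080 - 1), 0.05)
  fc <- fit_decay(kinetic_trace(seq(0, 100, 10), rep(2, 11)))
  expect_equal(fc$flag, "unidentifiable")
  expect_true(is.na(fc$taus))
})

test_that("actin half-times follow the interpolation definition", {
  # linear ramp 0 -> M over 10 min: t_half = 5 min
  t <- seq(0, 10, 0.5)
  ramp <- kinetic_trace(t, t / 10, time_unit = "min")
  ht <- actin_halftimes(list(ramp), window = 10, baseline_frames = 1)
  expect_equal(ht$halftimes$t_half, 5)
  # step at frame k: crossing within the bracketing frame interval
  step <- kinetic_trace(seq(0, 27, 3), c(0, 0, 0, rep(1, 7)),
                        time_unit = "min")
  hs <- actin_halftimes(list(step), baseline_frames = 2)
  expect_gt(hs$halftimes$t_half, 6)
  expect_lte(hs$halftimes$t_half, 9)
  # saturating rise, zero lag, fine sampling: analytic half-rise time
  tt <- seq(0, 27, 0.01)
  tau <- 4
  rise <- kinetic_trace(tt, 1 - exp(-tt / tau), time_unit = "min")
  hr <- actin_halftimes(list(rise), window = 27, baseline_frames = 1)
  m <- 1 - exp(-27 / tau)
  expect_equal(hr$halftimes$t_half, -tau * log(1 - m / 2), tolerance = 0.01)
  # no assembly flag
  flat <- kinetic_trace(seq(0, 27, 3), rep(0.5, 10), time_unit = "min")
  hf <- actin_halftimes(list(flat))
  expect_true(is.na(hf$halftimes$t_half))
  expect_equal(hf$halftimes$flag, "no assembly")
})

test_that("generated lags are uncorrelated with cluster size", {
  ds <- gen_actin_timecourse(n_clusters = 50, lag_range = c(6, 15),
                             duration = 30, seed = 17)
  res <- actin_halftimes(ds, window = 27)
  expect_true(all(!is.na(res$halftimes$t_half)))
  rho_area <- res$correlations$rho[res$correlations$variable == "area_um2"]
  p_area <- res$correlations$p_value[res$correlations$variable == "area_um2"]
  expect_lt(abs(rho_area), 0.3)
  expect_gt(p_area, 0.05)
})
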