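#' Kinetic intensity trace
#'
#' Container for FRAP, dissociation and actin-assembly time courses: strictly
#' increasing times with finite intensity values, an optional count of leading
#' pre-bleach (pre-perturbation) frames, an optional reference trace recording
#' acquisition photobleaching, and an optional background (scalar or trace).
#'
#' @param times time points, strictly increasing (seconds, or minutes for
#'   actin data; see `time_unit`).
#' @param values intensities (raw or normalized), finite.
#' @param n_prebleach number of leading frames acquired before the
#'   perturbation.
#' @param reference optional reference trace (same length) measuring
#'   acquisition bleaching without the bleach pulse.
#' @param background scalar or trace of background intensity.
#' @param time_unit `"s"` or `"min"`.
#' @return A list of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, values, n_prebleach = 0L, reference = NULL,
                          background = 0, time_unit = "s") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(values))) stop("values must be finite")
  if (!is.null(reference) && length(reference) != length(values))
    stop("reference length must match values")
  if (n_prebleach < 0 || n_prebleach > length(times))
    stop("invalid n_prebleach")
  structure(list(times = times, values = values,
                 n_prebleach = as.integer(n_prebleach),
                 reference = reference, background = background,
                 time_unit = time_unit),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("kinetic_trace: %d frames over %.4g %s (%d pre-bleach)\n",
              length(x$times), max(x$times) - min(x$times), x$time_unit,
              x$n_prebleach))
  invisible(x)
}

#' Locate the bleach frame of a raw trace
#'
#' Returns the index of the first frame whose value drops more than 3 SD below
#' the mean of the preceding frames; used when a trace arrives without an
#' explicit pre-bleach frame count.
#'
#' @param trace a [kinetic_trace()].
#' @param min_pre minimum number of frames used for the running baseline.
#' @return Frame index of the bleach, or `NA` if no drop is found.
#' @export
find_bleach_frame <- function(trace, min_pre = 3L) {
  v <- trace$values
  for (i in (min_pre + 1L):length(v)) {
    pre <- v[seq_len(i - 1L)]
    s <- stats::sd(pre)
    if (s > 0 && v[i] < mean(pre) - 3 * s) return(i)
  }
  NA_integer_
}

#' Normalize a FRAP trace
#'
#' Background-subtracts the trace, divides by the (equally
#' background-subtracted) reference trace to remove acquisition bleaching, and
#' scales so that the mean of the pre-bleach frames is 1:
#' `out(t) = [(I(t) - bg) / (ref(t) - bg)] / mean_prebleach`. Without a
#' reference trace the reference quotient is 1. `mode = "subtract"` instead
#' removes the reference's fractional decay additively before the pre-bleach
#' scaling.
#'
#' @param trace a [kinetic_trace()] with at least 2 pre-bleach frames.
#' @param mode `"divide"` (default) or `"subtract"`.
#' @return A normalized [kinetic_trace()] (pre-bleach mean exactly 1,
#'   background 0, reference removed).
#' @export
normalize_frap <- function(trace, mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  if (trace$n_prebleach < 2) stop("at least 2 pre-bleach frames are required")
  bg <- trace$background
  v <- trace$values - bg
  pre <- seq_len(trace$n_prebleach)
  if (!is.null(trace$reference)) {
    r <- trace$reference - bg
    if (any(r <= 0)) stop("reference must exceed background everywhere")
    if (mode == "divide") {
      v <- v / r
    } else {
      v <- v - (r - mean(r[pre]))
    }
  }
  m <- mean(v[pre])
  if (m <= 0) stop("non-positive pre-bleach mean")
  kinetic_trace(trace$times, v / m, n_prebleach = trace$n_prebleach,
                reference = NULL, background = 0, time_unit = trace$time_unit)
}

# Multistart Levenberg-Marquardt least squares on a model function; returns
# the fit with smallest deviance, or NULL. The raw optimizer is used rather
# than an nls wrapper because collapsed bi-exponential solutions (equal time
# constants, or one amplitude at its zero bound) have a rank-deficient
# Jacobian that a wrapper refuses even though the least-squares solution is
# perfectly usable.
best_nls <- function(y, model, starts, lower) {
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = function(p) y - model(p),
                         lower = lower,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(f) && is.finite(stats::deviance(f)) &&
        (is.null(best) || stats::deviance(f) < stats::deviance(best)))
      best <- f
  }
  best
}

exp_fit_obj <- function(fit, n_components, n_obs, kind = "recovery",
                        flag = NULL) {
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(co)))
  names(se) <- names(co)
  if (n_components == 2) {
    taus <- c(co[["tau1"]], co[["tau2"]])
    amps <- c(co[["A1"]], co[["A2"]])
    o <- order(taus)
    taus <- taus[o]; amps <- amps[o]
  } else {
    taus <- co[["tau"]]; amps <- co[["A"]]
  }
  n_params <- length(co)
  plateau <- if ("plateau" %in% names(co)) co[["plateau"]] else co[["C"]]
  structure(list(n_components = n_components, taus = unname(taus),
                 amplitudes = unname(amps),
                 fractions = unname(amps / sum(amps)),
                 plateau = unname(plateau),
                 bleach_floor = unname(plateau - sum(amps)),
                 ss_residual = stats::deviance(fit),
                 df = n_obs - n_params,
                 sigma = sqrt(stats::deviance(fit) / max(1, n_obs - n_params)),
                 ci95 = cbind(estimate = co, lower = co - 1.96 * se,
                              upper = co + 1.96 * se),
                 kind = kind, flag = flag),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%d-component exponential %s fit\n", x$n_components, x$kind))
  for (i in seq_along(x$taus))
    cat(sprintf("  tau%d = %.4g (%.0f%%)\n", i, x$taus[i],
                100 * x$fractions[i]))
  cat(sprintf("  plateau %.4g, SS %.4g, df %d\n", x$plateau, x$ss_residual,
              x$df))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Fit exponential recovery to a FRAP trace
#'
#' Nonlinear least squares of
#' `f(t) = plateau - sum_i A_i exp(-t / tau_i)` to the post-bleach frames,
#' with time measured from the first post-bleach frame. Bi-exponential fits
#' are initialization-sensitive, so a multistart grid over
#' `tau in {T/100, T/10, T/3}` and amplitude fractions `{0.25, 0.5, 0.75}`
#' (plus starts derived from the single-component solution) is used and the
#' smallest-SS fit kept. Amplitude fractions are reported as fractions of the
#' total recovering amplitude.
#'
#' @param trace a normalized [kinetic_trace()] (see [normalize_frap()]).
#' @param n_components 1 or 2.
#' @return An object of class `exp_fit` with elements `n_components`, `taus`
#'   (ascending), `amplitudes`, `fractions`, `plateau`, `bleach_floor`
#'   (fitted value at the bleach instant), `ss_residual`, `df`, `sigma`,
#'   `ci95`, `flag` (non-`NULL` when a time constant sits at a bound).
#' @export
fit_recovery <- function(trace, n_components = 2L) {
  if (!n_components %in% 1:2) stop("n_components must be 1 or 2")
  post <- (trace$n_prebleach + 1L):length(trace$times)
  s <- trace$times[post] - trace$times[post][1]
  y <- trace$values[post]
  n_params <- 1L + 2L * n_components
  if (length(y) < 3L * n_params)
    stop("too few post-bleach points for the requested model")
  if (max(y) - min(y) < 1e-10 * max(abs(y), 1))
    stop("zero recovering amplitude: trace is constant")
  t_total <- max(s)
  plateau0 <- mean(utils::tail(y, max(3L, round(length(y) / 10))))
  A0 <- plateau0 - y[1]
  if (A0 <= 0) A0 <- max(plateau0 - min(y), 0.1 * max(abs(y)))
  tau_grid <- t_total / c(100, 10, 3)
  if (n_components == 1L) {
    starts <- lapply(tau_grid, function(t0)
      list(plateau = plateau0, A = A0, tau = t0))
    fit <- best_nls(y, function(p) p$plateau - p$A * exp(-s / p$tau), starts,
                    lower = c(-Inf, 0, 1e-12))
    if (is.null(fit)) stop("single-exponential fit did not converge")
    out <- exp_fit_obj(fit, 1L, length(y))
  } else {
    starts <- list()
    pairs <- utils::combn(tau_grid, 2, simplify = FALSE)
    for (pr in pairs) for (fr in c(0.25, 0.5, 0.75))
      starts[[length(starts) + 1L]] <- list(plateau = plateau0,
                                            A1 = fr * A0, A2 = (1 - fr) * A0,
                                            tau1 = pr[1], tau2 = pr[2])
    f1 <- tryCatch(fit_recovery(trace, 1L), error = function(e) NULL)
    if (!is.null(f1)) {
      starts[[length(starts) + 1L]] <- list(plateau = f1$plateau,
                                            A1 = 0.99 * f1$amplitudes,
                                            A2 = 0.01 * f1$amplitudes,
                                            tau1 = f1$taus, tau2 = 10 * f1$taus)
      starts[[length(starts) + 1L]] <- list(plateau = f1$plateau,
                                            A1 = 0.5 * f1$amplitudes,
                                            A2 = 0.5 * f1$amplitudes,
                                            tau1 = f1$taus / 5,
                                            tau2 = 5 * f1$taus)
    }
    fit <- best_nls(y, function(p)
      p$plateau - p$A1 * exp(-s / p$tau1) - p$A2 * exp(-s / p$tau2),
      starts, lower = c(-Inf, 0, 0, 1e-12, 1e-12))
    if (is.null(fit)) stop("bi-exponential fit did not converge")
    out <- exp_fit_obj(fit, 2L, length(y))
  }
  if (any(out$taus <= 1e-11) || any(out$taus > 1e3 * t_total))
    out$flag <- "time constant at bound"
  out
}

#' Nested-model F-test between single and double exponential fits
#'
#' `F = [(SS1 - SS2) / (df1 - df2)] / (SS2 / df2)` with p-value from the F
#' distribution on `(df1 - df2, df2)` degrees of freedom; the richer model is
#' preferred when `p < alpha`.
#'
#' @param fit1 the simpler (nested) `exp_fit`.
#' @param fit2 the richer `exp_fit`; must have fewer residual df than `fit1`.
#' @param alpha significance level.
#' @return A list of class `model_choice`: `F_stat`, `df_num`, `df_den`,
#'   `p_value`, `preferred` (`"single"` or `"double"`), `perfect_fit` flag.
#' @export
select_model <- function(fit1, fit2, alpha = 0.05) {
  if (fit1$df <= fit2$df)
    stop("fit1 must be the nested model (more residual degrees of freedom)")
  df_num <- fit1$df - fit2$df
  df_den <- fit2$df
  if (fit2$ss_residual <= 0) {
    return(structure(list(F_stat = Inf, df_num = df_num, df_den = df_den,
                          p_value = 0, preferred = "double",
                          perfect_fit = TRUE),
                     class = "model_choice"))
  }
  Fstat <- max(0, ((fit1$ss_residual - fit2$ss_residual) / df_num) /
                 (fit2$ss_residual / df_den))
  p <- stats::pf(Fstat, df_num, df_den, lower.tail = FALSE)
  structure(list(F_stat = Fstat, df_num = df_num, df_den = df_den,
                 p_value = p,
                 preferred = if (p < alpha) "double" else "single",
                 perfect_fit = FALSE),
            class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat(sprintf("F (%d, %d) = %.4g, p = %.3g -> preferred model: %s\n",
              x$df_num, x$df_den, x$F_stat, x$p_value, x$preferred))
  invisible(x)
}

#' Fit a mono-exponential decay
#'
#' Fits `I(t) = A exp(-t / tau) + C`, the model for slow dissociation of
#' His-tagged protein from the bilayer. A constant trace is returned with
#' `tau = NA` and an `"unidentifiable"` flag rather than an error.
#'
#' @param trace a [kinetic_trace()] with at least 5 points.
#' @return An `exp_fit` (with `kind = "decay"`; `plateau` holds the offset C).
#' @export
fit_decay <- function(trace) {
  t <- trace$times; y <- trace$values
  if (length(y) < 5) stop("at least 5 points are required")
  rng <- max(y) - min(y)
  if (rng < 1e-10 * max(abs(y), 1)) {
    return(structure(list(n_components = 1L, taus = NA_real_,
                          amplitudes = 0, fractions = 1,
                          plateau = mean(y), bleach_floor = mean(y),
                          ss_residual = sum((y - mean(y))^2),
                          df = length(y) - 3L, sigma = stats::sd(y),
                          ci95 = NULL, kind = "decay",
                          flag = "unidentifiable"),
                     class = "exp_fit"))
  }
  C0 <- min(y); A0 <- max(y) - C0
  ypos <- pmax(y - C0 + 0.05 * A0, 1e-12 * A0)
  sl <- stats::coef(stats::lm(log(ypos) ~ t))[2]
  tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else max(t) / 3
  starts <- lapply(unique(c(tau0, max(t) / 10, max(t) / 3)), function(tt)
    list(A = A0, tau = tt, C = C0))
  fit <- best_nls(y, function(p) p$A * exp(-t / p$tau) + p$C,
                  starts, lower = c(0, 1e-12, -Inf))
  if (is.null(fit)) stop("decay fit did not converge")
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  structure(list(n_components = 1L, taus = unname(co[["tau"]]),
                 amplitudes = unname(co[["A"]]), fractions = 1,
                 plateau = unname(co[["C"]]),
                 bleach_floor = unname(co[["C"]] + co[["A"]]),
                 ss_residual = stats::deviance(fit), df = length(y) - 3L,
                 sigma = sqrt(stats::deviance(fit) / (length(y) - 3L)),
                 ci95 = cbind(estimate = co, lower = co - 1.96 * se,
                              upper = co + 1.96 * se),
                 kind = "decay", flag = NULL),
            class = "exp_fit")
}

#' Per-cluster actin assembly half-times
#'
#' For each trace, subtracts the initial baseline, finds the maximum within
#' the analysis window (default the first 27 min), and returns the time at
#' which the signal first reaches halfway between baseline and maximum, by
#' linear interpolation between the bracketing frames. Traces never exceeding
#' twice their baseline are flagged (`no assembly`; `t_half = NA`). When
#' per-cluster features are supplied, Spearman rank correlations of `t_half`
#' with cluster area and receptor intensity are reported.
#'
#' @param traces list of [kinetic_trace()] (times in minutes), or an
#'   `actin_dataset` from [gen_actin_timecourse()].
#' @param cluster_features optional data frame with columns `area_um2` and
#'   `receptor_intensity`, one row per trace.
#' @param window analysis window (min).
#' @param baseline_frames number of initial frames averaged as the baseline.
#' @return A list with `halftimes` (data frame `cluster`, `t_half`, `flag`,
#'   plus any features) and `correlations` (data frame `variable`, `rho`,
#'   `p_value`; `NULL` without features).
#' @export
actin_halftimes <- function(traces, cluster_features = NULL, window = 27,
                            baseline_frames = 2L) {
  if (inherits(traces, "actin_dataset")) {
    if (is.null(cluster_features)) cluster_features <- traces$features
    traces <- traces$traces
  }
  n <- length(traces)
  t_half <- rep(NA_real_, n)
  flag <- character(n)
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    sel <- tr$times <= window
    t <- tr$times[sel]; v <- tr$values[sel]
    b <- mean(v[seq_len(min(baseline_frames, length(v)))])
    m <- max(v)
    if (m < 2 * b) {
      flag[i] <- "no assembly"
      next
    }
    half <- b + (m - b) / 2
    k <- which(v >= half)[1]
    if (k == 1L) {
      t_half[i] <- t[1]
    } else {
      t_half[i] <- t[k - 1] + (half - v[k - 1]) / (v[k] - v[k - 1]) *
        (t[k] - t[k - 1])
    }
    flag[i] <- ""
  }
  out <- data.frame(cluster = seq_len(n), t_half = t_half, flag = flag)
  correlations <- NULL
  if (!is.null(cluster_features)) {
    out <- cbind(out, cluster_features[setdiff(names(cluster_features),
                                               names(out))])
    ok <- !is.na(t_half)
    corrow <- function(var) {
      ct <- suppressWarnings(stats::cor.test(t_half[ok],
                                             cluster_features[[var]][ok],
                                             method = "spearman"))
      data.frame(variable = var, rho = unname(ct$estimate),
                 p_value = ct$p.value)
    }
    vars <- intersect(c("area_um2", "receptor_intensity"),
                      names(cluster_features))
    correlations <- do.call(rbind, lapply(vars, corrow))
  }
  list(halftimes = out, correlations = correlations)
}
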