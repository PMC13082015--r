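#' @title Indicator biophysics
#' @description Step-response exponential kinetics, the fluorescence-voltage
#'   sigmoid, spike-waveform metrics and the sampling-rate (downsampling)
#'   analysis.
#' @name biophys
NULL

# ---- step-response kinetics -------------------------------------------------

#' Fit piecewise multi-exponential kinetics to a step response
#'
#' Fits `F(t) = sum_i k_i exp((t - t0) lambda_i) + c` for `t > t0` and the
#' flat pre-step level `sum_i k_i + c` for `t <= t0`, with rate terms
#' `lambda_i = -1 / tau_i`. Components slower than `slow_tau_s` are flagged
#' as photobleaching and excluded from the reported kinetic fractions.
#'
#' @param trace a `vs_trace` cropped around a single step event.
#' @param order number of exponential components (1-3).
#' @param t0_s optional onset initialization; defaults to the steepest point
#'   of the trace.
#' @param slow_tau_s components with tau above this are treated as slow
#'   photobleaching, not kinetics (default 0.25 s).
#' @return an `exp_kinetics_fit` list: `k`, `lambda` (= -1/tau), `tau_ms`,
#'   `c`, `t0`, `order`, kinetic `fractions` (over non-bleach components),
#'   `bleach_flag` per component and a `predict(t)` function.
#' @export
fit_step_kinetics <- function(trace, order = 1, t0_s = NULL,
                              slow_tau_s = 0.25) {
  stopifnot(inherits(trace, "vs_trace"), order %in% 1:3)
  t <- trace_time(trace)
  y <- trace$values
  if (stats::sd(y) < 1e-12 * max(abs(mean(y)), 1)) {
    # constant trace: no kinetics, plateau at the mean
    return(structure(list(k = rep(0, order), lambda = rep(-1, order),
                          tau_ms = rep(1000, order), c = mean(y),
                          t0 = t[1], order = order,
                          fractions = rep(1 / order, order),
                          bleach_flag = rep(FALSE, order),
                          predict = function(tt) rep(mean(y), length(tt))),
                     class = "exp_kinetics_fit"))
  }
  if (is.null(t0_s)) {
    # locate the onset on a ~1-ms smoothed copy so noise does not move it
    ys <- moving_average(y, max(3L, round(0.001 * trace$rate)))
    t0_s <- t[which.max(abs(diff(ys)))]
  }
  if (t0_s < t[1] || t0_s > t[length(t)])
    stop("contract error: t0 outside the cropped trace", call. = FALSE)
  span <- t[length(t)] - t0_s
  # log-linear tail initialization for the dominant tau
  post <- t > t0_s
  amp_tot <- y[which(post)[1]] - y[length(y)]
  c0 <- y[length(y)]
  tau0 <- {
    yy <- abs(y[post] - c0)
    # fit the log decay only down to 20% of the initial amplitude, so the
    # noise floor does not flatten the slope
    a0 <- max(yy[seq_len(min(50, length(yy)))])
    below <- which(yy < 0.2 * a0)
    sel <- seq_len(max(10, if (length(below)) below[1] else length(yy)))
    fit <- stats::lm(log(yy[sel] + 1e-12) ~ t[post][sel])
    tau <- -1 / stats::coef(fit)[2]
    if (!is.finite(tau) || tau <= 0 || tau > span) span / 5 else tau
  }
  rhs <- paste(sprintf(
    "k%d * exp(-pmax(t - t0, 0) / tau%d)", seq_len(order), seq_len(order)),
    collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs, "+ cc"))
  # the onset is constrained to a few ms around its derivative-based
  # estimate: the crop convention places the event there, and a free t0
  # lets the fast component absorb onset error into a spurious tau
  t0_slack <- 0.003
  lower <- c(rep(-Inf, order), rep(1e-6, order), -Inf,
             max(t[1], t0_s - t0_slack))
  upper <- c(rep(Inf, order), rep(Inf, order), Inf,
             min(t[length(t)], t0_s + t0_slack))
  # multi-start: spread tau initializations (coincident starting time
  # constants make the Jacobian singular) and keep the lowest-RSS fit
  mk_start <- function(taus)
    as.list(c(stats::setNames(rep(amp_tot / order, order),
                              paste0("k", seq_len(order))),
              stats::setNames(pmin(pmax(taus, 2e-6), span),
                              paste0("tau", seq_len(order))),
              cc = c0, t0 = t0_s))
  starts <- lapply(c(2, 4, 10, 30), function(spread)
    mk_start(tau0 * spread^(seq_len(order) - (order + 1) / 2)))
  fit <- NULL
  best_rss <- Inf
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(t = t, y = y),
                        start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (rss < best_rss) { best_rss <- rss; fit <- f }
    }
  }
  if (is.null(fit)) stop("fit error: kinetics fit did not converge",
                         call. = FALSE)
  pars <- as.list(stats::coef(fit))
  k <- unlist(pars[paste0("k", seq_len(order))])
  tau <- unlist(pars[paste0("tau", seq_len(order))])
  cc <- pars$cc
  bleach_flag <- tau > slow_tau_s
  kin <- !bleach_flag
  fractions <- rep(NA_real_, order)
  if (any(kin)) fractions[kin] <- abs(k[kin]) / sum(abs(k[kin]))
  o <- order # capture for the closure
  structure(list(k = unname(k), lambda = unname(-1 / tau),
                 tau_ms = unname(tau * 1000), c = cc, t0 = pars$t0,
                 order = order, fractions = unname(fractions),
                 bleach_flag = unname(bleach_flag),
                 predict = function(tt) {
                   out <- rep(cc, length(tt))
                   for (i in seq_len(o))
                     out <- out + k[i] * exp(-pmax(tt - pars$t0, 0) / tau[i])
                   out
                 }),
            class = "exp_kinetics_fit")
}

# ---- fluorescence-voltage sigmoid ------------------------------------------

#' Fit the fluorescence-voltage logistic sigmoid
#'
#' Fits `F(x) = L / (1 + exp(-k (x - x0))) + b` to steady-state (mV, dF/F)
#' points, then translates the curve so that `F(-70 mV) = 0`, the resting
#' anchor convention. Anchoring is idempotent.
#'
#' @param points data frame with columns `mV` and `dff` (at least 5 voltage
#'   levels spanning the inflection).
#' @param anchor_mV anchoring voltage (default -70).
#' @return a `sigmoid_fv_fit` list with `L`, `k_slope`, `x0`, `b`
#'   (post-anchoring), the anchoring `offset` applied, and `predict(v)`.
#' @export
fit_fv_sigmoid <- function(points, anchor_mV = -70) {
  stopifnot(is.data.frame(points), all(c("mV", "dff") %in% names(points)),
            nrow(points) >= 5)
  x <- points$mV; y <- points$dff
  if (stats::sd(y) < 1e-12 * max(abs(mean(y)), 1)) {
    L <- 0; k <- 0.01; x0 <- mean(x); b <- 0
    return(structure(list(L = L, k_slope = k, x0 = x0, b = b, offset = 0,
                          predict = function(v) rep(0, length(v))),
                     class = "sigmoid_fv_fit"))
  }
  rng <- max(y) - min(y)
  start <- list(L = 2 * rng, k = 4 / (max(x) - min(x)), x0 = mean(x),
                b = min(y) - rng / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (x - x0))) + b,
                      data = data.frame(x = x, y = y), start = start,
                      lower = c(-Inf, 1e-6, -Inf, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("fit error: sigmoid fit did not converge; check monotonicity",
         call. = FALSE)
  p <- as.list(stats::coef(fit))
  f_anchor <- p$L / (1 + exp(-p$k * (anchor_mV - p$x0))) + p$b
  b_new <- p$b - f_anchor
  pred <- function(v) p$L / (1 + exp(-p$k * (v - p$x0))) + b_new
  stopifnot(abs(pred(anchor_mV)) < 1e-9)
  structure(list(L = p$L, k_slope = p$k, x0 = p$x0, b = b_new,
                 offset = -f_anchor, predict = pred),
            class = "sigmoid_fv_fit")
}

# ---- spike waveform metrics -------------------------------------------------

#' Amplitude, FWHM and decay constant of an average spike waveform
#'
#' Amplitude is measured from the onset point to the peak on the raw
#' waveform. FWHM is the extent in time at half-maximum amplitude, taken
#' after linear interpolation to `interp_rate` (default 20 kHz). The decay
#' constant is a single-exponential fit to the repolarization phase, from
#' the peak until the waveform returns within 10% of baseline.
#'
#' @param sta a `vs_trace` holding the averaged spike waveform.
#' @param interp_rate interpolation rate for the FWHM measurement (Hz).
#' @param onset_index sample index of the spike onset; defaults to the last
#'   sample before the peak at or below the pre-peak baseline.
#' @return a `spike_metrics` list: `amplitude`, `fwhm_ms` (NA with
#'   `fwhm_defined = FALSE` when the waveform never falls below half-max),
#'   `tau_off_ms`, `onset_index`, `peak_index`.
#' @export
spike_metrics <- function(sta, interp_rate = 20000, onset_index = NULL) {
  stopifnot(inherits(sta, "vs_trace"))
  y <- sta$values
  t <- trace_time(sta)
  peak_i <- which.max(y)
  base <- stats::median(y[seq_len(max(2, floor(length(y) * 0.1)))])
  if (is.null(onset_index)) {
    pre <- which(y[seq_len(peak_i - 1)] <= base)
    onset_index <- if (length(pre)) max(pre) else 1L
  }
  amplitude <- y[peak_i] - y[onset_index]
  half <- y[onset_index] + amplitude / 2
  # 20 kHz linear interpolation for the width measurement only
  ti <- seq(t[1], t[length(t)], by = 1 / interp_rate)
  yi <- stats::approx(t, y, xout = ti)$y
  pk_i2 <- which.max(yi)
  up <- which(yi[seq_len(pk_i2)] < half)
  down <- which(yi[pk_i2:length(yi)] < half)
  if (length(up) == 0 || length(down) == 0) {
    fwhm_ms <- NA_real_; fwhm_defined <- FALSE
  } else {
    cross <- function(i0, i1) {    # linear crossing time between samples
      if (yi[i1] == yi[i0]) return(ti[i1])
      ti[i0] + (half - yi[i0]) / (yi[i1] - yi[i0]) * (ti[i1] - ti[i0])
    }
    iu <- max(up)
    id <- pk_i2 + min(down) - 1
    fwhm_ms <- (cross(id - 1, id) - cross(iu, iu + 1)) * 1000
    fwhm_defined <- TRUE
  }
  # repolarization fit: peak until return within 10% of baseline
  ret <- which(y[peak_i:length(y)] <= base + 0.1 * amplitude)
  end_i <- if (length(ret)) peak_i + min(ret) - 1 else length(y)
  tau_off_ms <- NA_real_
  if (end_i - peak_i >= 3) {
    td <- t[peak_i:end_i] - t[peak_i]
    yd <- y[peak_i:end_i]
    fit <- tryCatch(
      minpack.lm::nlsLM(yd ~ A * exp(-td / tau) + C,
                        start = list(A = amplitude, tau = max(td) / 3,
                                     C = base),
                        lower = c(-Inf, 1e-9, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) tau_off_ms <- stats::coef(fit)[["tau"]] * 1000
  }
  structure(list(amplitude = amplitude, fwhm_ms = fwhm_ms,
                 fwhm_defined = fwhm_defined, tau_off_ms = tau_off_ms,
                 onset_index = onset_index, peak_index = peak_i),
            class = "spike_metrics")
}

# ---- downsampling analysis --------------------------------------------------

#' Peak-amplitude loss and variability under temporal downsampling
#'
#' The waveform is linearly upsampled to `up_rate` (default 1 MHz) and then
#' resampled at each requested rate at `n_phases` starting-point offsets
#' spanning one output sampling period. Per rate, the mean and coefficient
#' of variation of the sampled peak are reported, normalized to the
#' original waveform maximum.
#'
#' @param waveform a `vs_trace` (typically an average spike waveform).
#' @param rates sampling rates to test (Hz); must not exceed `up_rate`.
#' @param n_phases number of temporal phases per rate (default 20).
#' @param up_rate intermediate upsampling rate (default 1e6).
#' @return data frame with columns `rate_hz`, `peak_mean`, `peak_cv`.
#' @export
downsampling_analysis <- function(waveform, rates, n_phases = 20,
                                  up_rate = 1e6) {
  stopifnot(inherits(waveform, "vs_trace"))
  if (any(rates > up_rate))
    stop("config error: rate exceeds the upsampling rate", call. = FALSE)
  t <- trace_time(waveform)
  y <- waveform$values
  peak0 <- max(y)
  ti <- seq(t[1], t[length(t)], by = 1 / up_rate)
  yi <- stats::approx(t, y, xout = ti)$y
  res <- lapply(sort(rates, decreasing = TRUE), function(r) {
    period <- 1 / r
    peaks <- vapply(seq_len(n_phases), function(ph) {
      off <- (ph - 1) / n_phases * period
      ts <- seq(t[1] + off, t[length(t)], by = period)
      max(stats::approx(ti, yi, xout = ts, rule = 2)$y)
    }, numeric(1))
    peaks <- peaks / peak0
    data.frame(rate_hz = r, peak_mean = mean(peaks),
               peak_cv = stats::sd(peaks) / mean(peaks))
  })
  do.call(rbind, res)
}
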