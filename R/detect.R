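#' @title Optical spike detection and event post-processing
#' @description Three detectors (adaptive kernel-density threshold,
#'   delayed-differential kHz-rate detector, sliding-standard-deviation
#'   detector) plus singlet isolation, spike-triggered averages, rolling
#'   rates, SNR variants, shot-noise discriminability and subthreshold
#'   fluctuation quantification.
#' @name detect
NULL

#' Detected spike train
#'
#' @param index sample indices of event peaks (strictly increasing).
#' @param rate sampling rate of the parent trace (Hz).
#' @param amplitude per-event amplitude or z-score.
#' @param detector detector name.
#' @param config detector configuration list.
#' @param threshold threshold actually applied.
#' @param onset_times_s optional per-event onset times.
#' @return an object of class `vs_spikes`; event times follow the
#'   frame-center convention.
#' @export
vs_spikes <- function(index, rate, amplitude = rep(NA_real_, length(index)),
                      detector = "manual", config = list(),
                      threshold = NA_real_, onset_times_s = NULL) {
  index <- as.integer(index)
  stopifnot(length(index) < 2 || all(diff(index) > 0), all(index >= 1))
  structure(list(times_s = (index - 0.5) / rate, index = index,
                 amplitude = amplitude, rate = rate, detector = detector,
                 config = config, threshold = threshold,
                 onset_times_s = onset_times_s),
            class = "vs_spikes")
}

#' @export
print.vs_spikes <- function(x, ...) {
  cat(sprintf("<vs_spikes> %d events (%s detector)\n",
              length(x$index), x$detector))
  invisible(x)
}

#' @export
length.vs_spikes <- function(x) length(x$index)

# ---- adaptive KDE detector --------------------------------------------------

#' Adaptive threshold from the kernel-density of peak amplitudes
#'
#' Estimates the probability density of first-pass peak amplitudes with a
#' Gaussian KDE, models the noise distribution by reflecting the KDE around
#' the median amplitude (assuming symmetric noise), computes the tail
#' integrals `Fmax(x)` (true KDE) and `Fnoise(x)` (reflected KDE) on an
#' amplitude grid and returns the grid point maximizing the score
#' `g(x) = Fmax(x)^p - Fnoise(x)^p`. Ties resolve to the smallest
#' amplitude. Bandwidth uses Scott's rule; the grid has `grid_n` points
#' spanning the peak-amplitude range.
#'
#' @param peaks numeric vector of peak amplitudes (>= 10).
#' @param p stringency parameter in (0, 1], default 0.1.
#' @param grid_n amplitude grid size (default 512).
#' @return a list with `threshold`, the `grid`, and `g` evaluated on it.
#' @export
adaptive_kde_threshold <- function(peaks, p = 0.1, grid_n = 512) {
  stopifnot(p > 0, p <= 1)
  if (length(peaks) < 10)
    stop("insufficient-statistics error: fewer than 10 peaks",
         call. = FALSE)
  med <- stats::median(peaks)
  bw <- stats::bw.nrd(peaks)
  grid <- seq(min(peaks), max(peaks), length.out = grid_n)
  refl <- 2 * med - peaks
  # exact Gaussian-KDE tail integrals (mixture of normal upper tails)
  tail_int <- function(centers)
    vapply(grid, function(x0)
      mean(stats::pnorm((x0 - centers) / bw, lower.tail = FALSE)),
      numeric(1))
  fmax <- tail_int(peaks)
  fnoise <- tail_int(refl)
  g <- fmax^p - fnoise^p
  list(threshold = grid[which.max(g)], grid = grid, g = g,
       fmax = fmax, fnoise = fnoise)
}

#' Adaptive-KDE spike detection
#'
#' High-pass filters the trace (default 20 Hz), runs a first-pass local
#' maxima detection, derives the adaptive threshold from the peak-amplitude
#' distribution via [adaptive_kde_threshold()], and keeps peaks above
#' `threshold * scale`.
#'
#' @param trace a `vs_trace` at least 2 s long.
#' @param cfg list with `hp_hz` (20), `p` (0.1), `scale` (1), `grid_n`
#'   (512), `min_sep` (2 samples).
#' @return a `vs_spikes` train; the applied threshold is recorded.
#' @export
detect_adaptive_kde <- function(trace, cfg = list()) {
  stopifnot(inherits(trace, "vs_trace"),
            length(trace$values) / trace$rate >= 2)
  hp_hz <- cfg$hp_hz %||% 20
  p <- cfg$p %||% 0.1
  scale <- cfg$scale %||% 1
  grid_n <- cfg$grid_n %||% 512
  min_sep <- cfg$min_sep %||% 2L
  y <- butter_filter(trace$values, trace$rate, hp_hz, "high", order = 2,
                     zero_phase = FALSE)
  pk <- local_maxima(y, min_sep)
  th <- adaptive_kde_threshold(y[pk], p = p, grid_n = grid_n)
  keep <- pk[y[pk] > th$threshold * scale]
  vs_spikes(keep, trace$rate, amplitude = y[keep],
            detector = "adaptive_kde",
            config = list(hp_hz = hp_hz, p = p, scale = scale,
                          grid_n = grid_n, min_sep = min_sep),
            threshold = th$threshold * scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- delayed-differential kHz detector --------------------------------------

# Rolling linear-regression slope over a centered window of `w` samples.
rolling_slope <- function(y, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  x <- seq_len(w) - (w + 1) / 2
  num <- stats::filter(y, rev(x), sides = 2)
  as.numeric(num) / sum(x^2)
}

#' Delayed-differential spike detection for kHz-rate photon-count traces
#'
#' The trace is high-pass filtered (default 40 Hz, 2nd order), converted to
#' a delayed-differential contrast: the difference between a "signal" mean
#' over `signal_ms` and a "baseline" mean over `baseline_ms` delayed by
#' `delay_ms` (so the baseline excludes the rising phase of a putative
#' spike). The contrast is sharpened by multiplying with the positive part
#' of the trace's high-frequency content (cutoff `hf_hz`) and z-scored;
#' samples above `z_thresh` standard deviations, merged within `merge_ms`,
#' form events. Event onsets are the local peak of the rolling
#' linear-regression slope over `onset_slope_ms` computed on a
#' linearly-interpolated copy of the trace at `interp_rate`.
#'
#' @param trace a `vs_trace` sampled at >= 2x `hf_hz`.
#' @param cfg list overriding `hp_hz` (40), `signal_ms` (2), `baseline_ms`
#'   (3), `delay_ms` (1), `hf_hz` (250), `z_thresh` (20), `merge_ms` (1),
#'   `onset_slope_ms` (3), `interp_rate` (10000).
#' @return a `vs_spikes` train with z-score amplitudes and onset times.
#' @export
detect_ulove <- function(trace, cfg = list()) {
  stopifnot(inherits(trace, "vs_trace"))
  hp_hz <- cfg$hp_hz %||% 40
  signal_ms <- cfg$signal_ms %||% 2
  baseline_ms <- cfg$baseline_ms %||% 3
  delay_ms <- cfg$delay_ms %||% 1
  hf_hz <- cfg$hf_hz %||% 250
  z_thresh <- cfg$z_thresh %||% 20
  merge_ms <- cfg$merge_ms %||% 1
  onset_slope_ms <- cfg$onset_slope_ms %||% 3
  interp_rate <- cfg$interp_rate %||% 10000
  rate <- trace$rate
  if (rate < 2 * hf_hz)
    stop("config error: sampling rate below 2x the high-frequency cutoff",
         call. = FALSE)
  # zero-phase filtering preserves the optical spike's amplitude and
  # timing; a causal filter attenuates the transient enough to defeat the
  # fixed 20-SD event rule
  y <- butter_filter(trace$values, rate, hp_hz, "high", order = 2,
                     zero_phase = TRUE)
  w_sig <- max(1L, round(signal_ms / 1000 * rate))
  w_bl <- max(1L, round(baseline_ms / 1000 * rate))
  d <- max(1L, round(delay_ms / 1000 * rate))
  sig <- trailing_mean(y, w_sig)
  bl_full <- trailing_mean(y, w_bl)
  bl <- c(rep(bl_full[1], d), bl_full[seq_len(length(y) - d)])
  dd <- sig - bl
  # sharpen with the positive high-frequency content of the differential
  hf <- pmax(butter_filter(dd, rate, hf_hz, "high", order = 2,
                           zero_phase = TRUE), 0)
  contrast <- dd * hf
  z <- (contrast - mean(contrast)) / stats::sd(contrast)
  above <- z > z_thresh
  if (!any(above)) {
    return(vs_spikes(integer(0), rate, numeric(0), detector = "ulove",
                     config = cfg, threshold = z_thresh,
                     onset_times_s = numeric(0)))
  }
  # group supra-threshold runs, merging gaps shorter than merge_ms
  idx <- which(above)
  gap <- max(1L, round(merge_ms / 1000 * rate))
  brk <- c(0, which(diff(idx) > gap), length(idx))
  ev <- integer(0)
  for (k in seq_len(length(brk) - 1)) {
    run <- idx[(brk[k] + 1):brk[k + 1]]
    ev <- c(ev, run[which.max(z[run])])
  }
  # onsets: peak of the regression slope on an interpolated copy
  t <- trace_time(trace)
  ti <- seq(t[1], t[length(t)], by = 1 / interp_rate)
  yi <- stats::approx(t, trace$values, xout = ti)$y
  sl <- rolling_slope(yi, round(onset_slope_ms / 1000 * interp_rate))
  sl[is.na(sl)] <- 0
  onsets <- vapply(ev, function(i) {
    tev <- t[i]
    win <- which(ti >= tev - 0.005 & ti <= tev + 0.001)
    if (length(win) == 0) return(tev)
    ti[win[which.max(sl[win])]]
  }, numeric(1))
  vs_spikes(ev, rate, amplitude = z[ev], detector = "ulove", config = cfg,
            threshold = z_thresh, onset_times_s = onsets)
}

# ---- sliding-standard-deviation detector ------------------------------------

#' Sliding-standard-deviation spike detection with inverted-trace
#' false-positive calibration
#'
#' The dF/F trace is detrended with a high-pass Butterworth filter (default
#' 3rd order, 15 Hz) and local maxima exceeding `k_sigma` times the sliding
#' standard deviation of the detrended trace are events. The same analysis
#' on the sign-inverted trace estimates the false-positive rate as the
#' ratio of inverted to upright event counts.
#'
#' @param trace a `vs_trace` of dF/F.
#' @param cfg list overriding `hp_hz` (15), `order` (3), `k_sigma` (3.5),
#'   `window_s` (1), `min_sep` (2 samples).
#' @return list with `spikes` (a `vs_spikes`), `fp_rate_estimate` and the
#'   inverted-trace event count.
#' @export
detect_sliding_std <- function(trace, cfg = list()) {
  stopifnot(inherits(trace, "vs_trace"))
  hp_hz <- cfg$hp_hz %||% 15
  ord <- cfg$order %||% 3
  k_sigma <- cfg$k_sigma %||% 3.5
  window_s <- cfg$window_s %||% 1
  min_sep <- cfg$min_sep %||% 2L
  w <- round(window_s * trace$rate)
  if (w < 10) stop("config error: sliding window under 10 samples",
                   call. = FALSE)
  det <- butter_filter(trace$values, trace$rate, hp_hz, "high",
                       order = ord, zero_phase = FALSE)
  sl_sd <- rolling_sd(det, w)
  count_events <- function(x) {
    pk <- local_maxima(x, min_sep)
    pk[x[pk] > k_sigma * sl_sd[pk]]
  }
  up <- count_events(det)
  inv <- count_events(-det)
  fp <- if (length(up) > 0) length(inv) / length(up) else NA_real_
  list(spikes = vs_spikes(up, trace$rate, amplitude = det[up],
                          detector = "sliding_std", config = cfg,
                          threshold = k_sigma),
       fp_rate_estimate = fp, inverted_count = length(inv))
}

# ---- event post-processing --------------------------------------------------

#' Keep only bilaterally isolated events (singlets)
#' @param train a `vs_spikes`.
#' @param gap_ms required clearance before and after each event (commonly
#'   50 or 100 ms depending on the acquisition context).
#' @return a `vs_spikes` containing the isolated subset.
#' @export
isolate_singlets <- function(train, gap_ms = 100) {
  stopifnot(inherits(train, "vs_spikes"))
  ts <- train$times_s
  n <- length(ts)
  if (n == 0) return(train)
  gap <- gap_ms / 1000
  prev_ok <- c(TRUE, diff(ts) >= gap)
  next_ok <- c(diff(ts) >= gap, TRUE)
  keep <- prev_ok & next_ok
  out <- train
  out$times_s <- ts[keep]
  out$index <- train$index[keep]
  out$amplitude <- train$amplitude[keep]
  if (!is.null(train$onset_times_s))
    out$onset_times_s <- train$onset_times_s[keep]
  out
}

#' Spike-triggered average with per-event baseline subtraction
#'
#' Events are mapped to the nearest frame center; a snippet of
#' `window_s = c(pre, post)` seconds is cut per event and a per-event
#' baseline subtracted before averaging. Two baseline rules are supported:
#' `"pre20frames"` uses the mean of the 20 frames ending 5 frames before
#' the event peak, computed on a spike-interpolated copy of the trace
#' (linear interpolation across +/- `interp_frames` frames around every
#' event, so spike transients do not bias the baseline); `"pre500ms"`
#' subtracts each snippet's own mean from -500 ms to 0 ms. Events whose
#' window falls outside the trace are dropped and counted.
#'
#' @param trace a `vs_trace`.
#' @param train a `vs_spikes` (or numeric event times in seconds).
#' @param window_s `c(pre, post)` in seconds.
#' @param baseline_rule `"pre20frames"` or `"pre500ms"`.
#' @param interp_frames half-width (frames) of the spike-interpolation span
#'   used by the `"pre20frames"` rule.
#' @return list with `sta` (a `vs_trace` starting at -pre), `sem`,
#'   `n_events`, `n_dropped`, and the per-event snippet matrix.
#' @export
spike_triggered_average <- function(trace, train,
                                    window_s = c(0.5, 0.5),
                                    baseline_rule = c("pre20frames",
                                                      "pre500ms"),
                                    interp_frames = 2L) {
  baseline_rule <- match.arg(baseline_rule)
  stopifnot(inherits(trace, "vs_trace"))
  times <- if (inherits(train, "vs_spikes")) train$times_s else train
  rate <- trace$rate
  y <- trace$values
  n <- length(y)
  centers <- pmin(pmax(round(times * rate + 0.5), 1L), n)
  pre <- round(window_s[1] * rate)
  post <- round(window_s[2] * rate)
  ok <- centers - pre >= 1 & centers + post <= n &
    centers - 25 >= 1   # pre20frames window must also fit
  n_dropped <- sum(!ok)
  centers <- centers[ok]
  if (length(centers) == 0)
    stop("empty-result error: no event with a full window inside the trace",
         call. = FALSE)
  y_interp <- y
  if (baseline_rule == "pre20frames") {
    mask <- rep(FALSE, n)
    for (c0 in centers) {
      lo <- max(1, c0 - interp_frames)
      hi <- min(n, c0 + interp_frames)
      mask[lo:hi] <- TRUE
    }
    if (any(mask) && !all(mask)) {
      idx <- which(!mask)
      y_interp <- stats::approx(idx, y[idx], xout = seq_len(n),
                                rule = 2)$y
    }
  }
  snip <- matrix(NA_real_, length(centers), pre + post + 1)
  for (i in seq_along(centers)) {
    c0 <- centers[i]
    s <- y[(c0 - pre):(c0 + post)]
    bl <- if (baseline_rule == "pre20frames")
      mean(y_interp[(c0 - 24):(c0 - 5)])
    else
      mean(s[seq_len(pre)])
    snip[i, ] <- s - bl
  }
  sta <- colMeans(snip)
  sem <- apply(snip, 2, stats::sd) / sqrt(nrow(snip))
  list(sta = vs_trace(sta, rate, trace$units, t0 = -pre / rate),
       sem = sem, n_events = length(centers), n_dropped = n_dropped,
       snippets = snip)
}

# ---- SNR variants -----------------------------------------------------------

#' Per-event spike signal-to-noise ratio
#'
#' Three noise conventions:
#' * `"resonant_baseline"`: each event's 200-ms snippet is normalized by
#'   subtracting the mean of the -75 to -25 ms window preceding the peak;
#'   signal is the snippet peak, noise the SD of that same window.
#' * `"shot_noise"`: requires photon-count units; per-event dF/F amplitude
#'   (peak over local baseline) divided by the shot noise of dF/F,
#'   `1 / sqrt(mean count per frame)` — equivalently amplitude in photons
#'   over the square root of the mean photon count.
#' * `"dynamic_spikefree"`: the trace is high-pass filtered at 0.25 Hz and
#'   then 20 Hz; a local mean over a +/-1 s window clips upward deviations
#'   and the noise is twice the SD of the remaining downward deviations
#'   over a +/-5 s window; the SNR trace is the detrended signal over this
#'   dynamic noise, sampled at event times.
#'
#' @param trace a `vs_trace`.
#' @param train a `vs_spikes`.
#' @param method noise convention.
#' @return an `snr_report` list with `method`, `per_event`, `mean`, and the
#'   noise estimate(s) used.
#' @export
spike_snr <- function(trace, train,
                      method = c("resonant_baseline", "shot_noise",
                                 "dynamic_spikefree")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "vs_trace"), inherits(train, "vs_spikes"))
  y <- trace$values
  rate <- trace$rate
  idx <- train$index
  if (method == "resonant_baseline") {
    w_pre_lo <- round(0.075 * rate); w_pre_hi <- round(0.025 * rate)
    half <- round(0.1 * rate)
    per <- vapply(idx, function(i) {
      if (i - w_pre_lo < 1 || i + half > length(y)) return(NA_real_)
      base_win <- y[(i - w_pre_lo):(i - w_pre_hi)]
      snip <- y[(i - half):(i + half)] - mean(base_win)
      noise <- stats::sd(base_win)
      if (noise <= 0) return(NA_real_)
      max(snip) / noise
    }, numeric(1))
    res <- list(noise = NA_real_)
  } else if (method == "shot_noise") {
    if (trace$units != "photons")
      stop("unit error: shot-noise SNR requires photon counts",
           call. = FALSE)
    mu <- mean(y)
    w_pre_lo <- round(0.075 * rate); w_pre_hi <- max(1, round(0.025 * rate))
    per <- vapply(idx, function(i) {
      lo <- max(1, i - w_pre_lo); hi <- max(1, i - w_pre_hi)
      amp_dff <- (y[i] - mean(y[lo:hi])) / mu
      amp_dff * sqrt(mu)
    }, numeric(1))
    res <- list(noise = 1 / sqrt(mu), mean_count = mu)
  } else {
    det <- butter_filter(y, rate, 0.25, "high", order = 2,
                         zero_phase = FALSE)
    det <- butter_filter(det, rate, 20, "high", order = 2,
                         zero_phase = FALSE)
    lm1 <- moving_average(det, round(2 * rate))     # +/- 1 s window
    down <- pmin(det - lm1, 0)
    noise_t <- 2 * rolling_sd(down, round(10 * rate))  # +/- 5 s window
    noise_t[noise_t <= 0] <- NA_real_
    snr_trace <- det / noise_t
    per <- snr_trace[idx]
    res <- list(noise_trace = noise_t)
  }
  structure(c(list(method = method, per_event = per,
                   mean = mean(per, na.rm = TRUE)), res),
            class = "snr_report")
}

#' Shot-noise-limited spike discriminability
#'
#' `d' = (dF/F spike amplitude) * sqrt(photons collected over the spike
#' integration window)`, with the window taken as the optical spike FWHM.
#' This combines response amplitude with the photon budget: doubling the
#' flux scales d' by sqrt(2), doubling the amplitude doubles it.
#'
#' @param trace a `vs_trace` in photon-count units.
#' @param amplitude_dff spike amplitude as dF/F.
#' @param window_ms integration window (optical FWHM) in ms.
#' @return scalar d-prime.
#' @export
dprime <- function(trace, amplitude_dff, window_ms) {
  stopifnot(inherits(trace, "vs_trace"))
  if (trace$units != "photons")
    stop("unit error: d-prime requires photon counts", call. = FALSE)
  n_photons <- mean(trace$values) * trace$rate * window_ms / 1000
  amplitude_dff * sqrt(n_photons)
}

#' Rolling spike rate normalized to the first minute
#'
#' Counts events in a centered rolling window (default 1 minute, stepped
#' every 250 ms) and divides by the mean rate of the first minute.
#'
#' @param train a `vs_spikes` (or numeric times in s).
#' @param duration_s recording length; must be >= `window_s`.
#' @param window_s rolling window (default 60 s).
#' @param step_s step between window centers (default 0.25 s).
#' @return data frame with `t_s` (window centers) and `rate_norm`.
#' @export
rolling_spike_rate <- function(train, duration_s, window_s = 60,
                               step_s = 0.25) {
  times <- if (inherits(train, "vs_spikes")) train$times_s else train
  stopifnot(duration_s >= window_s)
  first_min <- sum(times <= window_s) / window_s
  if (first_min == 0)
    stop("normalization undefined: no events in the first window",
         call. = FALSE)
  centers <- seq(window_s / 2, duration_s - window_s / 2, by = step_s)
  counts <- vapply(centers, function(c0)
    sum(times >= c0 - window_s / 2 & times < c0 + window_s / 2),
    numeric(1))
  data.frame(t_s = centers, rate_norm = counts / window_s / first_min)
}

#' Subthreshold fluctuation magnitude (high state minus low state)
#'
#' The trace is band-pass filtered 0.1-50 Hz (zero-phase) and restricted to
#' samples where the animal's speed is below `speed_cut_cms`. The low state
#' is the 1st percentile of the filtered, speed-masked trace; the high
#' state is the median of the filtered trace at the detected spike onsets;
#' the magnitude is their difference.
#'
#' @param trace a `vs_trace`.
#' @param train a `vs_spikes` with onset times (falls back to event times).
#' @param speed a `vs_trace` of running speed (cm/s), interpolated to the
#'   trace rate if needed; `NULL` disables the speed mask.
#' @param speed_cut_cms speed threshold (default 1 cm/s).
#' @param band_hz band edges, default `c(0.1, 50)`.
#' @return list with `low_state`, `high_state`, `magnitude`.
#' @export
subthreshold_fluctuation <- function(trace, train, speed = NULL,
                                     speed_cut_cms = 1,
                                     band_hz = c(0.1, 50)) {
  stopifnot(inherits(trace, "vs_trace"), inherits(train, "vs_spikes"))
  f <- butter_bandpass(trace$values, trace$rate, band_hz[1], band_hz[2],
                       order = 2, zero_phase = TRUE)
  mask <- rep(TRUE, length(f))
  if (!is.null(speed)) {
    sp <- stats::approx(trace_time(speed), speed$values,
                        xout = trace_time(trace), rule = 2)$y
    mask <- sp < speed_cut_cms
  }
  if (!any(mask))
    stop("masked-empty error: no samples below the speed cutoff",
         call. = FALSE)
  low <- stats::quantile(f[mask], 0.01, names = FALSE)
  onset_t <- train$onset_times_s %||% train$times_s
  onset_i <- pmin(pmax(round(onset_t * trace$rate + 0.5), 1L), length(f))
  high <- stats::median(f[onset_i])
  list(low_state = low, high_state = high, magnitude = high - low)
}
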