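#' @title Stimulus-locked functional analysis
#' @description Direction regressors, pixelwise orientation tuning by
#'   complex projection, tuning curves, visual-responsiveness tests, PSTHs,
#'   and the slow-oscillation phase binning / cross-correlation analyses
#'   for multiplexed voltage-neuromodulator recordings.
#' @name funcmap
NULL

#' Direction regressor matrix for stimulus-locked regression
#'
#' Each unique direction gets a column evaluating, at the frame centers,
#' `R(t) = (1 - exp(-max(0, t - t_onset)/tau)) -
#'         (1 - exp(-max(0, t - t_offset)/tau))`
#' summed over that direction's (non-overlapping) trials: an exponential
#' rise from stimulus onset that relaxes back after offset.
#'
#' @param schedule data frame with `onset_s`, `offset_s`, `direction_deg`.
#' @param frame_times frame-center timestamps (s).
#' @param tau regressor time constant (s), default 0.7.
#' @return matrix `length(frame_times) x n_directions` with the sorted
#'   unique directions as column names.
#' @export
build_regressors <- function(schedule, frame_times, tau = 0.7) {
  stopifnot(all(c("onset_s", "offset_s", "direction_deg") %in%
                  names(schedule)))
  dirs <- sort(unique(schedule$direction_deg))
  X <- matrix(0, length(frame_times), length(dirs),
              dimnames = list(NULL, as.character(dirs)))
  for (j in seq_along(dirs)) {
    trials <- schedule[schedule$direction_deg == dirs[j], ]
    for (k in seq_len(nrow(trials))) {
      r <- (1 - exp(-pmax(0, frame_times - trials$onset_s[k]) / tau)) -
        (1 - exp(-pmax(0, frame_times - trials$offset_s[k]) / tau))
      X[, j] <- X[, j] + r
    }
  }
  X
}

#' Detrend and normalize a movie for pixelwise regression
#'
#' Per pixel: subtract a low-pass filtered copy (default 0.1 Hz) and divide
#' by it (detrending), then center on the mean and divide by the
#' root-sum-of-squares of the pixel's temporal trace.
#'
#' @param movie a `vs_movie`.
#' @param detrend_hz low-pass cutoff for the slow trend; `NULL` skips the
#'   divide-by-trend stage (useful when the movie is already dF/F-like).
#' @return a `vs_movie` of normalized pixel time series.
#' @export
normalize_movie_pixels <- function(movie, detrend_hz = 0.1) {
  stopifnot(inherits(movie, "vs_movie"))
  d <- dim(movie$data)
  flat <- matrix(movie$data, nrow = d[1])
  if (!is.null(detrend_hz) && detrend_hz < movie$rate / 2) {
    for (j in seq_len(ncol(flat))) {
      lp <- butter_filter(flat[, j], movie$rate, detrend_hz, "low",
                          order = 2, zero_phase = TRUE)
      if (all(lp > 0)) flat[, j] <- (flat[, j] - lp) / lp
      else flat[, j] <- flat[, j] - lp
    }
  }
  mu <- colMeans(flat)
  flat <- sweep(flat, 2, mu)
  rss <- sqrt(colSums(flat^2))
  rss[rss == 0] <- 1
  flat <- sweep(flat, 2, rss, "/")
  vs_movie(array(flat, d), movie$rate, movie$saturation)
}

#' Pixelwise orientation tuning map by complex projection
#'
#' Regresses every pixel's normalized time series on the direction
#' regressor matrix (ordinary least squares, which reduces to the matrix
#' projection when the regressors are orthogonal), then projects the
#' per-direction coefficients onto the complex basis `exp(2i theta)`
#' scaled by `1/sqrt(N/2)`. The phase of the resulting complex number is
#' the pixel's preferred orientation (mod pi); the magnitude is the tuning
#' strength. A perfectly direction-symmetric response cancels exactly.
#'
#' @param movie a normalized `vs_movie` (see [normalize_movie_pixels()]).
#' @param regressors matrix from [build_regressors()].
#' @param directions_deg directions (deg) matching the regressor columns.
#' @return a `tuning_map` list: `orientation` (radians in `[0, pi)`),
#'   `amplitude`, `z` (complex matrix) and an `hsv` rendering spec (hue =
#'   orientation, saturation/value = normalized amplitude).
#' @export
pixelwise_tuning <- function(movie, regressors, directions_deg) {
  stopifnot(inherits(movie, "vs_movie"),
            ncol(regressors) == length(directions_deg))
  if (qr(regressors)$rank < ncol(regressors))
    stop("design error: regressor matrix is rank-deficient", call. = FALSE)
  d <- dim(movie$data)
  Y <- matrix(movie$data, nrow = d[1])
  coef <- qr.solve(regressors, Y)     # n_directions x n_pixels
  theta <- directions_deg * pi / 180
  basis <- exp(2i * theta) / sqrt(length(theta) / 2)
  zvec <- as.vector(basis %*% coef)
  z <- matrix(zvec, d[2], d[3])
  ori <- (Arg(z) / 2) %% pi
  amp <- Mod(z)
  amax <- max(amp)
  structure(list(orientation = ori, amplitude = amp, z = z,
                 hsv = list(h = ori / pi, s = amp / max(amax, 1e-12),
                            v = amp / max(amax, 1e-12))),
            class = "tuning_map")
}

#' Trial-averaged tuning curve
#'
#' Mean dF/F during each direction's stimulation windows, with SEM across
#' trials. Directions with no trials are flagged.
#'
#' @param dff a `vs_trace`.
#' @param schedule data frame with `onset_s`, `offset_s`, `direction_deg`.
#' @return data frame with `direction_deg`, `mean_dff`, `sem`, `n_trials`.
#' @export
tuning_curve <- function(dff, schedule) {
  stopifnot(inherits(dff, "vs_trace"))
  t <- trace_time(dff)
  dirs <- sort(unique(schedule$direction_deg))
  rows <- lapply(dirs, function(d0) {
    trials <- schedule[schedule$direction_deg == d0, ]
    vals <- vapply(seq_len(nrow(trials)), function(k) {
      sel <- t >= trials$onset_s[k] & t <= trials$offset_s[k]
      if (!any(sel)) NA_real_ else mean(dff$values[sel])
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    data.frame(direction_deg = d0, mean_dff = mean(vals),
               sem = stats::sd(vals) / sqrt(length(vals)),
               n_trials = length(vals))
  })
  do.call(rbind, rows)
}

#' Visual responsiveness by per-direction one-tailed t-tests
#'
#' For every direction, trial responses during the stimulation window are
#' compared with the matched blank-window responses by a one-tailed Welch
#' t-test (alternative: stimulation greater). A cell is visually
#' responsive if any direction's p-value falls below
#' `alpha / n_directions` (Bonferroni-corrected family level).
#'
#' @param trace a `vs_trace` (spike-rate or subthreshold dF/F).
#' @param schedule data frame with `onset_s` (cycle start), `direction_deg`.
#' @param stim_window stimulation window relative to cycle onset (s),
#'   default `c(0.5, 1.3)`.
#' @param blank_window blank window relative to cycle onset, default
#'   `c(0.3, 0.5)`.
#' @param extend_s extra time appended to the stimulation window (used for
#'   subthreshold responses to capture stimulus-offset responses).
#' @param alpha family-wise error target (default 0.05).
#' @return list with `vr` (logical verdict), `p_values` per direction and
#'   the corrected threshold.
#' @export
visual_responsiveness <- function(trace, schedule,
                                  stim_window = c(0.5, 1.3),
                                  blank_window = c(0.3, 0.5),
                                  extend_s = 0, alpha = 0.05) {
  stopifnot(inherits(trace, "vs_trace"))
  t <- trace_time(trace)
  dirs <- sort(unique(schedule$direction_deg))
  pvals <- vapply(dirs, function(d0) {
    trials <- schedule[schedule$direction_deg == d0, ]
    if (nrow(trials) < 2)
      stop("precondition error: need >= 2 trials per direction",
           call. = FALSE)
    stim <- vapply(trials$onset_s, function(on)
      mean(trace$values[t >= on + stim_window[1] &
                          t <= on + stim_window[2] + extend_s]),
      numeric(1))
    blank <- vapply(trials$onset_s, function(on)
      mean(trace$values[t >= on + blank_window[1] &
                          t <= on + blank_window[2]]),
      numeric(1))
    if (stats::sd(c(stim, blank)) == 0) return(1)
    stats::t.test(stim, blank, alternative = "greater")$p.value
  }, numeric(1))
  thr <- alpha / length(dirs)
  list(vr = any(pvals < thr), p_values = stats::setNames(pvals, dirs),
       threshold = thr)
}

#' Peri-stimulus time histogram
#'
#' Bins spike times relative to alignment events and converts counts to a
#' mean rate per alignment (Hz).
#'
#' @param trains list of `vs_spikes` (or numeric time vectors), pooled.
#' @param align_times alignment event times (s).
#' @param window `c(pre, post)` seconds around each alignment.
#' @param bin_ms bin width (default 10 ms).
#' @return data frame with `t_s` (bin centers) and `rate_hz`.
#' @export
psth <- function(trains, align_times, window = c(0.5, 1), bin_ms = 10) {
  if (!is.list(trains)) trains <- list(trains)
  times <- unlist(lapply(trains, function(tr)
    if (inherits(tr, "vs_spikes")) tr$times_s else tr))
  bw <- bin_ms / 1000
  breaks <- seq(-window[1], window[2], by = bw)
  counts <- numeric(length(breaks) - 1)
  for (a in align_times) {
    rel <- times - a
    rel <- rel[rel >= -window[1] & rel < window[2]]
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, breaks),
                                  nbins = length(counts))
  }
  n_align <- max(length(align_times), 1)
  data.frame(t_s = breaks[-length(breaks)] + bw / 2,
             rate_hz = counts / (n_align * bw))
}

# ---- multimodal phase analysis ----------------------------------------------

#' Bin voltage-band amplitude by the phase of a slow modulator
#'
#' The voltage trace is band-pass filtered 2-10 Hz (zero-phase Hamming
#' FIR), its Hilbert amplitude extracted and band-passed 0.1-1 Hz to match
#' the modulator's timescale. The modulator is band-passed 0.1-1 Hz and its
#' Hilbert phase computed. Within the supplied epochs, the filtered
#' amplitude is averaged in 65 phase bins spanning (-pi, pi], smoothed with
#' a circular 3-bin rolling average; empty bins carry NaN and are excluded
#' from smoothing.
#'
#' @param voltage_dff,modulator_dff co-sampled `vs_trace`s.
#' @param epochs list of `c(start_s, end_s)` behavioral epochs; `NULL`
#'   uses the full recording.
#' @param n_bins number of phase bins (default 65).
#' @param voltage_band,slow_band band edges in Hz.
#' @return a `phase_bin_profile` list: `phase` (bin centers), `mean`,
#'   `sem`, `mean_smooth`, `n` per bin.
#' @export
phase_bin_lowfreq <- function(voltage_dff, modulator_dff, epochs = NULL,
                              n_bins = 65, voltage_band = c(2, 10),
                              slow_band = c(0.1, 1)) {
  stopifnot(inherits(voltage_dff, "vs_trace"),
            inherits(modulator_dff, "vs_trace"),
            voltage_dff$rate == modulator_dff$rate,
            length(voltage_dff$values) == length(modulator_dff$values))
  rate <- voltage_dff$rate
  vb <- fir_bandpass(voltage_dff$values, rate, voltage_band[1],
                     voltage_band[2])
  amp <- hilbert_amplitude(vb)
  amp_f <- fir_bandpass(amp, rate, slow_band[1], slow_band[2])
  mod_f <- fir_bandpass(modulator_dff$values, rate, slow_band[1],
                        slow_band[2])
  phase <- hilbert_phase(mod_f)
  t <- trace_time(voltage_dff)
  sel <- if (is.null(epochs)) rep(TRUE, length(t)) else {
    s <- rep(FALSE, length(t))
    for (ep in epochs) s <- s | (t >= ep[1] & t <= ep[2])
    s
  }
  if (!any(sel)) stop("empty epochs", call. = FALSE)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(phase[sel], breaks,
                                rightmost.closed = TRUE), 1), n_bins)
  a <- amp_f[sel]
  mean_b <- sem_b <- rep(NaN, n_bins)
  n_b <- integer(n_bins)
  for (k in seq_len(n_bins)) {
    v <- a[bin == k]
    n_b[k] <- length(v)
    if (length(v)) {
      mean_b[k] <- mean(v)
      sem_b[k] <- stats::sd(v) / sqrt(length(v))
    }
  }
  # circular 3-bin rolling average over non-empty bins
  sm <- rep(NaN, n_bins)
  for (k in seq_len(n_bins)) {
    nb <- c((k - 2) %% n_bins + 1, k, k %% n_bins + 1)
    vals <- mean_b[nb]
    vals <- vals[!is.nan(vals)]
    if (length(vals)) sm[k] <- mean(vals)
  }
  structure(list(phase = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                 mean = mean_b, sem = sem_b, mean_smooth = sm, n = n_b),
            class = "phase_bin_profile")
}

#' Normalized cross-correlation and peak lag within a window
#'
#' Both traces are band-pass filtered (default 0.1-2 Hz), z-scored
#' (mean-subtracted, SD-divided), and their normalized cross-correlation
#' computed; the peak lag is searched within `max_lag_s` of zero (default
#' 3 s). A positive lag means `y` follows `x`.
#'
#' @param x,y co-sampled `vs_trace`s of equal length.
#' @param band_hz band edges (`NULL` skips filtering).
#' @param max_lag_s half-width of the lag search window.
#' @return list with `lag_s`, `cc` (correlation per lag), `peak_lag_s`,
#'   `peak_cc`.
#' @export
crosscorr_lag <- function(x, y, band_hz = c(0.1, 2), max_lag_s = 3) {
  stopifnot(inherits(x, "vs_trace"), inherits(y, "vs_trace"),
            x$rate == y$rate, length(x$values) == length(y$values))
  rate <- x$rate
  xv <- x$values; yv <- y$values
  if (!is.null(band_hz)) {
    xv <- fir_bandpass(xv, rate, band_hz[1], band_hz[2])
    yv <- fir_bandpass(yv, rate, band_hz[1], band_hz[2])
  }
  # population-SD normalization so the zero-lag autocorrelation is 1
  xv <- xv - mean(xv); xv <- xv / sqrt(mean(xv^2))
  yv <- yv - mean(yv); yv <- yv / sqrt(mean(yv^2))
  n <- length(xv)
  max_lag <- min(round(max_lag_s * rate), n - 2)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(xv[1:(n - k)] * yv[(1 + k):n]) / (n - k)
    else sum(xv[(1 - k):n] * yv[1:(n + k)]) / (n + k)
  }, numeric(1))
  pk <- which.max(cc)
  list(lag_s = lags / rate, cc = cc, peak_lag_s = lags[pk] / rate,
       peak_cc = cc[pk])
}

# ---- behavioral epoch selection ---------------------------------------------

# Runs where `x > thresh` for at least `min_s` seconds.
runs_above <- function(x, t, thresh, min_s) {
  above <- x > thresh
  if (!any(above)) return(matrix(numeric(0), 0, 2))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (t[ends] - t[starts]) >= min_s
  cbind(t[starts[keep]], t[ends[keep]])
}

#' Select quiet-wakefulness pupil epochs
#'
#' Identifies pupil dilation-constriction periods from a diameter series
#' (local minima to the next local minimum of a smoothed copy), retains
#' those whose dilation lasts over `min_dilation_s` and whose constriction
#' speed exceeds `min_constriction_mms`, and excludes periods that are 25%
#' or more NaN or that overlap a running period (speed above
#' `run_speed_cms` for at least `run_min_s`) extended by `run_pad_s` on
#' both sides. Each candidate carries an exclusion reason code.
#'
#' @param pupil a `vs_trace` of pupil diameter (mm; NaN where untracked).
#' @param running a `vs_trace` of locomotion speed (cm/s).
#' @param min_dilation_s,min_constriction_mms epoch admission rules.
#' @param nan_frac_max maximum tolerated NaN fraction (default 0.25).
#' @param run_speed_cms,run_min_s,run_pad_s running-period definition and
#'   exclusion padding.
#' @param smooth_s smoothing kernel for extremum detection.
#' @return data frame with `start_s`, `end_s`, `retained`, `reason`
#'   (`"ok"`, `"dilation_short"`, `"constriction_slow"`, `"nan_fraction"`,
#'   `"running"`).
#' @export
select_behavior_epochs <- function(pupil, running,
                                   min_dilation_s = 1,
                                   min_constriction_mms = 0.2,
                                   nan_frac_max = 0.25,
                                   run_speed_cms = 1, run_min_s = 1,
                                   run_pad_s = 3, smooth_s = 0.5) {
  stopifnot(inherits(pupil, "vs_trace"), inherits(running, "vs_trace"))
  t <- trace_time(pupil)
  d <- pupil$values
  d_fill <- d
  if (anyNA(d_fill)) {
    ok <- which(!is.na(d_fill))
    stopifnot(length(ok) >= 2)
    d_fill <- stats::approx(t[ok], d_fill[ok], xout = t, rule = 2)$y
  }
  ds <- moving_average(d_fill, round(smooth_s * pupil$rate))
  mins <- local_maxima(-ds, min_sep = max(2L, round(0.5 * pupil$rate)))
  maxs <- local_maxima(ds, min_sep = max(2L, round(0.5 * pupil$rate)))
  tr <- trace_time(running)
  run_iv <- runs_above(running$values, tr, run_speed_cms, run_min_s)
  if (nrow(run_iv)) {
    run_iv[, 1] <- run_iv[, 1] - run_pad_s
    run_iv[, 2] <- run_iv[, 2] + run_pad_s
  }
  out <- list()
  for (i in seq_along(mins)) {
    m0 <- mins[i]
    m2 <- mins[mins > m0]
    if (length(m2) == 0) break
    m2 <- m2[1]
    pk <- maxs[maxs > m0 & maxs < m2]
    if (length(pk) == 0) next
    pk <- pk[which.max(ds[pk])]
    dil_s <- t[pk] - t[m0]
    con_speed <- (ds[pk] - ds[m2]) / (t[m2] - t[pk])
    reason <- "ok"
    if (dil_s <= min_dilation_s) reason <- "dilation_short"
    else if (con_speed <= min_constriction_mms) reason <- "constriction_slow"
    else {
      nan_frac <- mean(is.na(d[m0:m2]))
      if (nan_frac >= nan_frac_max) reason <- "nan_fraction"
      else if (nrow(run_iv) &&
               any(run_iv[, 1] <= t[m2] & run_iv[, 2] >= t[m0]))
        reason <- "running"
    }
    out[[length(out) + 1]] <- data.frame(start_s = t[m0], end_s = t[m2],
                                         retained = reason == "ok",
                                         reason = reason)
  }
  if (length(out) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      retained = logical(0), reason = character(0)))
  do.call(rbind, out)
}
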