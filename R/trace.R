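#' Fluorescence / voltage trace container
#'
#' A `vs_trace` is a uniformly sampled 1-D series with a sampling rate and a
#' units flag. Timestamps follow the frame-center convention: sample `i`
#' covers `[(i-1)/rate, i/rate)` and is stamped at `(i - 0.5)/rate`.
#'
#' @param values numeric vector of samples.
#' @param rate sampling rate in Hz (> 0).
#' @param units one of `"au"` (arbitrary intensity), `"photons"`
#'   (photon counts), `"dff"` (fractional fluorescence change) or `"mV"`.
#' @param t0 time (s) of the leading edge of the first sample.
#' @return an object of class `vs_trace`.
#' @export
vs_trace <- function(values, rate, units = "au", t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1, rate > 0)
  structure(list(values = as.numeric(values), rate = rate,
                 units = units, t0 = t0),
            class = "vs_trace")
}

#' @export
print.vs_trace <- function(x, ...) {
  cat(sprintf("<vs_trace> %d samples @ %g Hz (%.3f s), units=%s\n",
              length(x$values), x$rate, length(x$values) / x$rate, x$units))
  invisible(x)
}

#' @export
length.vs_trace <- function(x) length(x$values)

#' Frame-center timestamps of a trace
#' @param x a `vs_trace`.
#' @return numeric vector of times in seconds.
#' @export
trace_time <- function(x) {
  stopifnot(inherits(x, "vs_trace"))
  x$t0 + (seq_along(x$values) - 0.5) / x$rate
}

as_trace <- function(x, rate, units = "au") {
  if (inherits(x, "vs_trace")) x else vs_trace(x, rate, units)
}

#' Movie container
#'
#' A 3-D fluorescence movie stored as an array `frames x rows x cols` with a
#' frame rate and an intensity ceiling used to flag saturated pixels.
#'
#' @param data numeric array with dimensions `(frames, rows, cols)`.
#' @param rate frame rate in Hz.
#' @param saturation intensity ceiling; pixels at or above it in any frame
#'   are treated as saturated.
#' @return an object of class `vs_movie`.
#' @export
vs_movie <- function(data, rate, saturation = Inf) {
  stopifnot(is.array(data), length(dim(data)) == 3, dim(data)[1] >= 1,
            rate > 0)
  structure(list(data = data, rate = rate, saturation = saturation),
            class = "vs_movie")
}

#' @export
print.vs_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vs_movie> %d frames of %d x %d @ %g Hz\n",
              d[1], d[2], d[3], x$rate))
  invisible(x)
}

#' Extract the mean trace over a pixel mask
#' @param movie a `vs_movie`.
#' @param mask logical matrix `rows x cols`.
#' @return a `vs_trace` of per-frame mean intensity over the mask.
#' @export
mask_trace <- function(movie, mask) {
  stopifnot(inherits(movie, "vs_movie"), is.matrix(mask))
  d <- dim(movie$data)
  stopifnot(all(dim(mask) == d[2:3]), any(mask))
  flat <- matrix(movie$data, nrow = d[1])
  vs_trace(rowMeans(flat[, as.vector(mask), drop = FALSE]), movie$rate)
}

# ---- filtering helpers ------------------------------------------------------

# Butterworth filter applied either causally or zero-phase (forward-backward).
butter_filter <- function(x, rate, cutoff_hz, type = c("high", "low"),
                          order = 2, zero_phase = TRUE) {
  type <- match.arg(type)
  w <- cutoff_hz / (rate / 2)
  stopifnot(w > 0, w < 1)
  b <- signal::butter(order, w, type)
  # remove the DC level first: filtfilt/filter start from zero state and a
  # large offset would otherwise produce edge transients
  xm <- mean(x)
  y <- if (zero_phase) filtfilt_padded(b, x - xm, rate, cutoff_hz) else
    as.numeric(signal::filter(b, x - xm))
  if (type == "low") y + xm else y
}

# Zero-phase filtering with odd-symmetric edge reflection, which
# suppresses the start/end transients of plain filtfilt.
filtfilt_padded <- function(b, x, rate, low_edge_hz) {
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * rate / low_edge_hz))
  if (pad < 2) return(signal::filtfilt(b, x))
  head_ref <- 2 * x[1] - rev(x[2:(pad + 1)])
  tail_ref <- 2 * x[n] - rev(x[(n - pad):(n - 1)])
  y <- signal::filtfilt(b, c(head_ref, x, tail_ref))
  y[(pad + 1):(pad + n)]
}

butter_bandpass <- function(x, rate, low_hz, high_hz, order = 2,
                            zero_phase = TRUE) {
  w <- c(low_hz, high_hz) / (rate / 2)
  stopifnot(all(w > 0), all(w < 1), low_hz < high_hz)
  b <- signal::butter(order, w, "pass")
  xm <- mean(x)
  if (zero_phase) filtfilt_padded(b, x - xm, rate, low_hz) else
    as.numeric(signal::filter(b, x - xm))
}

# Hamming-window FIR bandpass, zero-phase. Order defaults to 3x the longest
# period in the band so the slowest component is resolved by the kernel.
fir_bandpass <- function(x, rate, low_hz, high_hz, order = NULL) {
  if (is.null(order)) order <- ceiling(3 * rate / low_hz)
  order <- min(order, max(8, floor(length(x) / 3) - 1))
  if (order %% 2 == 1) order <- order + 1
  h <- signal::fir1(order, c(low_hz, high_hz) / (rate / 2), type = "pass",
                    window = signal::hamming(order + 1))
  signal::filtfilt(h, x - mean(x))   # h is an Ma filter object
}

# Analytic signal via FFT: standard frequency-domain construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hilbert_amplitude <- function(x) Mod(analytic_signal(x))
hilbert_phase <- function(x) Arg(analytic_signal(x))

# Centered moving average with edge shrinkage.
moving_average <- function(x, width) {
  width <- min(max(1L, as.integer(width)), length(x))
  k <- rep(1 / width, width)
  num <- stats::filter(x, k, sides = 2)
  # shrink the window at the edges instead of returning NA
  idx <- which(is.na(num))
  if (length(idx)) {
    half <- width %/% 2
    for (i in idx) {
      lo <- max(1, i - half)
      hi <- min(length(x), i + half)
      num[i] <- mean(x[lo:hi])
    }
  }
  as.numeric(num)
}

# Trailing (causal) moving average over `width` samples.
trailing_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  out[1:min(width, n)] <- cs[1:min(width, n)] / seq_len(min(width, n))
  if (n > width)
    out[(width + 1):n] <- (cs[(width + 1):n] - cs[1:(n - width)]) / width
  out
}

# Rolling standard deviation, centered, edge-shrunk; O(n) via cumsums.
rolling_sd <- function(x, width) {
  n <- length(x)
  width <- max(2L, as.integer(width))
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  m <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  v <- (s2 - s^2 / m) / pmax(m - 1, 1)
  sqrt(pmax(v, 0))
}

# Rolling quantile evaluated every `step` samples and linearly interpolated
# between evaluation points (exact when step == 1).
rolling_quantile <- function(x, width, prob, step = 1L) {
  n <- length(x)
  width <- min(max(2L, as.integer(width)), n)
  half <- width %/% 2
  centers <- unique(c(seq(1L, n, by = max(1L, as.integer(step))), n))
  q <- vapply(centers, function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    stats::quantile(x[lo:hi], prob, names = FALSE, type = 7)
  }, numeric(1))
  if (length(centers) == 1) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

# Linear interpolation of a trace onto a new rate (frame-center timestamps).
resample_linear <- function(x, rate_in, rate_out, t0 = 0) {
  t_in <- t0 + (seq_along(x) - 0.5) / rate_in
  n_out <- floor(length(x) * rate_out / rate_in)
  t_out <- t0 + (seq_len(n_out) - 0.5) / rate_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

# Strict local maxima with a minimum separation (in samples). Ties within the
# separation window keep the larger peak.
local_maxima <- function(x, min_sep = 2L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(idx) <= 1 || min_sep <= 1) return(idx)
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(n)
  taken <- logical(n)
  for (i in ord) {
    lo <- max(1, i - min_sep + 1)
    hi <- min(n, i + min_sep - 1)
    if (!any(taken[lo:hi])) {
      keep[i] <- TRUE
      taken[lo:hi] <- TRUE
    }
  }
  which(keep)
}
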