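#' @title High-throughput screening metrics
#' @description Per-field-of-view indicator scores: relative brightness,
#'   field-stimulation response amplitude, photostability AUC and the
#'   compound detectability metrics, aggregated per well by pixel-count
#'   weight.
#' @name screenmetrics
NULL

#' Relative indicator brightness against a co-expressed reference
#'
#' `B` is the mean fluorescence of the first `n_frames` frames of the
#' indicator (green) channel divided by the same quantity for the reference
#' protein (red) channel; the ratio normalizes out expression differences.
#'
#' @param green,red background-corrected `vs_trace`s of channel-summed
#'   fluorescence.
#' @param n_frames number of leading frames averaged (default 20).
#' @return scalar relative brightness `B`.
#' @export
relative_brightness <- function(green, red, n_frames = 20) {
  stopifnot(inherits(green, "vs_trace"), inherits(red, "vs_trace"),
            length(green$values) >= n_frames,
            length(red$values) >= n_frames)
  denom <- mean(red$values[seq_len(n_frames)])
  if (denom <= 0) stop("domain error: red-channel mean <= 0", call. = FALSE)
  mean(green$values[seq_len(n_frames)]) / denom
}

#' Field-stimulation response amplitude
#'
#' The trace is normalized by `F0` (mean of the first `baseline_s` seconds
#' of the bleach-corrected trace). `R` is the peak fractional response
#' `F/F0 - 1` in the window after the pulse, minus the standard deviation
#' of `F/F0` over the `baseline_s` seconds immediately preceding the pulse
#' (subtracted to discount baseline fluctuations).
#'
#' @param trace a bleach-corrected `vs_trace`.
#' @param pulse_time_s stimulation onset (s).
#' @param response_s length of the response window searched for the peak.
#' @param baseline_s length of both the F0 window and the pre-pulse window
#'   (default 0.1 s).
#' @return scalar response amplitude `R` (peak dF/F0 minus pre-pulse SD).
#' @export
response_amplitude <- function(trace, pulse_time_s, response_s = 0.2,
                               baseline_s = 0.1) {
  stopifnot(inherits(trace, "vs_trace"))
  t <- trace_time(trace)
  if (pulse_time_s <= baseline_s || pulse_time_s >= max(t))
    stop("index error: pulse window outside trace", call. = FALSE)
  f0 <- mean(trace$values[t <= baseline_s])
  norm <- trace$values / f0
  pre <- norm[t >= pulse_time_s - baseline_s & t < pulse_time_s]
  resp <- norm[t >= pulse_time_s & t <= pulse_time_s + response_s]
  if (length(resp) == 0)
    stop("index error: pulse window outside trace", call. = FALSE)
  max(resp) - 1 - stats::sd(pre)
}

#' Photostability as normalized area under the bleaching curve
#'
#' `P` is the trapezoid-rule area under the normalized fluorescence-vs-time
#' trace divided by the area of an ideal non-bleaching indicator (a straight
#' line at 1) over the same duration, so `P` lies in (0, 1] for decaying
#' traces.
#'
#' @param f_norm a `vs_trace` normalized to 1 at its first sample.
#' @return scalar photostability fraction `P`.
#' @export
photostability_auc <- function(f_norm) {
  stopifnot(inherits(f_norm, "vs_trace"))
  if (abs(f_norm$values[1] - 1) > 1e-6)
    stop("contract error: trace not normalized to 1 at t = 0",
         call. = FALSE)
  t <- trace_time(f_norm)
  pracma::trapz(t, f_norm$values) / (t[length(t)] - t[1])
}

#' Compound detectability metrics
#'
#' The detectability index combines response and brightness, the
#' detectability budget additionally discounts photobleaching through the
#' normalized photostability AUC (an average-over-initial brightness
#' factor): `DI = R * B^e`, `DB = R * (B * P)^e`. The brightness exponent
#' `e` defaults to 1/2, following the shot-noise-limited lineage of the
#' index (response resolvable against photon noise that grows as the square
#' root of the collected flux); a linear convention (`e = 1`) is also
#' supported.
#'
#' @param B relative brightness (>= 0).
#' @param R response amplitude.
#' @param P photostability AUC fraction in (0, 1].
#' @param exponent brightness exponent, 0.5 (default) or 1.
#' @return named list with `DI` and `DB`.
#' @export
detectability <- function(B, R, P, exponent = 0.5) {
  if (B < 0) stop("domain error: negative brightness", call. = FALSE)
  stopifnot(exponent %in% c(0.5, 1), P > 0, P <= 1)
  list(DI = R * B^exponent, DB = R * (B * P)^exponent)
}

#' Assemble a per-FOV screening record
#' @param B,R,P,n_pixels metric values and the pixel count of the FOV.
#' @param exponent brightness exponent passed to [detectability()].
#' @return a `screen_record` list with `B`, `R`, `P`, `DI`, `DB`,
#'   `n_pixels`.
#' @export
screen_record <- function(B, R, P, n_pixels, exponent = 0.5) {
  d <- detectability(B, R, P, exponent)
  structure(list(B = B, R = R, P = P, DI = d$DI, DB = d$DB,
                 n_pixels = n_pixels),
            class = "screen_record")
}

#' Aggregate FOV records into a well-level record
#'
#' Metrics are averaged across surviving fields of view with weights
#' proportional to each FOV's pixel count (FOV-area weighting).
#'
#' @param fov_records list of `screen_record`s (rejected FOVs removed
#'   beforehand).
#' @return a `screen_record` with pixel-weighted mean metrics and the total
#'   pixel count; errors if no FOV survives.
#' @export
aggregate_well <- function(fov_records) {
  fov_records <- Filter(Negate(is.null), fov_records)
  if (length(fov_records) == 0)
    stop("well flagged: all FOVs rejected", call. = FALSE)
  w <- vapply(fov_records, `[[`, numeric(1), "n_pixels")
  wm <- function(field) {
    v <- vapply(fov_records, `[[`, numeric(1), field)
    sum(v * w) / sum(w)
  }
  structure(list(B = wm("B"), R = wm("R"), P = wm("P"), DI = wm("DI"),
                 DB = wm("DB"), n_pixels = sum(w)),
            class = "screen_record")
}
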