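#' @title Ground-truth evaluation against electrophysiology
#' @description Spike matching at frame resolution, precision/recall/F1
#'   threshold curves, and subthreshold optical-electrical correspondence.
#' @name evaluate
NULL

# Truth spikes that are NOT bilaterally isolated by `isi_s` mark burst
# regions; returns the retained singlet times and the excluded intervals.
truth_singlets <- function(truth_times, isi_s = 0.1) {
  n <- length(truth_times)
  if (n == 0) return(list(singlets = truth_times,
                          excluded = matrix(numeric(0), 0, 2)))
  prev_ok <- c(TRUE, diff(truth_times) >= isi_s)
  next_ok <- c(diff(truth_times) >= isi_s, TRUE)
  keep <- prev_ok & next_ok
  excl <- truth_times[!keep]
  intervals <- if (length(excl))
    cbind(excl - isi_s, excl + isi_s) else matrix(numeric(0), 0, 2)
  list(singlets = truth_times[keep], excluded = intervals)
}

in_intervals <- function(x, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (k in seq_len(nrow(intervals)))
    out <- out | (x >= intervals[k, 1] & x <= intervals[k, 2])
  out
}

#' Match detected optical spikes against ground-truth spike times
#'
#' Ground-truth times (e.g. 10 kHz electrophysiology) are mapped to the
#' nearest imaging frame center. A true positive is a truth spike with an
#' optical event in the same or the subsequent `window_frames` frames;
#' matching is greedy earliest-first and one-to-one. Truth spikes inside
#' burst regions (inter-spike interval below `burst_isi_ms`) are excluded
#' from evaluation, as are optical events falling in those regions.
#'
#' @param truth_times_s ground-truth spike times (s).
#' @param optical a `vs_spikes` or numeric optical event times (s).
#' @param frame_rate imaging frame rate (Hz).
#' @param window_frames matching window beyond the same frame (default 2).
#' @param burst_isi_ms inter-spike interval below which truth spikes mark a
#'   burst region (default 100 ms); `NULL` skips the exclusion.
#' @return a `match_result` list: `TP`, `FP`, `FN`, `pairs` (data frame of
#'   matched truth/optical times), `tolerance_frames`, `n_truth` (singlets
#'   evaluated) and `truth_empty` flag.
#' @export
match_spikes <- function(truth_times_s, optical, frame_rate,
                         window_frames = 2, burst_isi_ms = 100) {
  opt_times <- if (inherits(optical, "vs_spikes")) optical$times_s
               else optical
  if (is.null(burst_isi_ms)) {
    singlets <- sort(truth_times_s)
    excl <- matrix(numeric(0), 0, 2)
  } else {
    ts <- truth_singlets(sort(truth_times_s), burst_isi_ms / 1000)
    singlets <- ts$singlets
    excl <- ts$excluded
  }
  opt_times <- sort(opt_times[!in_intervals(opt_times, excl)])
  to_frame <- function(t) round(t * frame_rate + 0.5)
  tf <- to_frame(singlets)
  of <- to_frame(opt_times)
  matched_opt <- rep(FALSE, length(of))
  pairs <- list()
  tp <- 0L
  for (i in seq_along(tf)) {
    cand <- which(!matched_opt & of >= tf[i] & of <= tf[i] + window_frames)
    if (length(cand)) {
      j <- cand[1]             # earliest-first
      matched_opt[j] <- TRUE
      tp <- tp + 1L
      pairs[[length(pairs) + 1]] <- c(singlets[i], opt_times[j])
    }
  }
  pairs <- if (length(pairs))
    stats::setNames(as.data.frame(do.call(rbind, pairs)),
                    c("ephys_time_s", "optical_time_s"))
  else data.frame(ephys_time_s = numeric(0), optical_time_s = numeric(0))
  structure(list(TP = tp, FP = sum(!matched_opt),
                 FN = length(tf) - tp, pairs = pairs,
                 tolerance_frames = window_frames,
                 n_truth = length(tf),
                 truth_empty = length(tf) == 0),
            class = "match_result")
}

#' Precision, recall and F1 from match counts
#'
#' Zero-division conventions: precision is 1 when no detections were made;
#' recall is 0 when truth spikes exist but none were found, and NA when the
#' truth is empty; F1 is 0 when precision + recall is 0.
#'
#' @param m a `match_result` (or a list with `TP`, `FP`, `FN`).
#' @return named list `precision`, `recall`, `f1`.
#' @export
precision_recall <- function(m) {
  tp <- m$TP; fp <- m$FP; fn <- m$FN
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Precision-recall curve over scaled adaptive thresholds
#'
#' Runs the adaptive-KDE detector once per recording, then sweeps a
#' multiplicative scale factor over its threshold, recomputing matching
#' counts at every scale.
#'
#' @param truth_times_s ground-truth spike times (s).
#' @param trace a `vs_trace` (imaging-rate fluorescence).
#' @param scales threshold scale factors (default 0.1 to 2.2 in 0.1 steps).
#' @param cfg adaptive detector configuration (see
#'   [detect_adaptive_kde()]).
#' @param window_frames,burst_isi_ms passed to [match_spikes()].
#' @return a `pr_curve` list: `table` (per-scale TP/FP/FN/precision/recall/
#'   F1), `best_scale` (max F1; smallest scale on ties), `degenerate` flag
#'   (all scales yield zero detections).
#' @export
pr_curve <- function(truth_times_s, trace,
                     scales = seq(0.1, 2.2, by = 0.1), cfg = list(),
                     window_frames = 2, burst_isi_ms = 100) {
  stopifnot(inherits(trace, "vs_trace"))
  hp_hz <- cfg$hp_hz %||% 20
  p <- cfg$p %||% 0.1
  grid_n <- cfg$grid_n %||% 512
  min_sep <- cfg$min_sep %||% 2L
  y <- butter_filter(trace$values, trace$rate, hp_hz, "high", order = 2,
                     zero_phase = FALSE)
  pk <- local_maxima(y, min_sep)
  th <- adaptive_kde_threshold(y[pk], p = p, grid_n = grid_n)$threshold
  rows <- lapply(scales, function(s) {
    keep <- pk[y[pk] > th * s]
    m <- match_spikes(truth_times_s, (keep - 0.5) / trace$rate,
                      trace$rate, window_frames, burst_isi_ms)
    pr <- precision_recall(m)
    data.frame(scale = s, TP = m$TP, FP = m$FP, FN = m$FN,
               precision = pr$precision, recall = pr$recall, f1 = pr$f1,
               n_detected = length(keep))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 best_scale = tab$scale[which.max(tab$f1)],
                 best_f1 = max(tab$f1),
                 degenerate = all(tab$n_detected == 0),
                 threshold = th),
            class = "pr_curve")
}

#' Pool precision-recall curves across recordings
#'
#' TP, FP and FN counts are summed across recordings at each scale factor
#' before recomputing precision, recall and F1; the population-uniform
#' scale is the one maximizing the pooled F1.
#'
#' @param curves list of `pr_curve` objects over identical scale grids.
#' @return a `pr_curve` over the pooled counts.
#' @export
pool_pr_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  scales <- curves[[1]]$table$scale
  for (cv in curves) stopifnot(all(cv$table$scale == scales))
  tp <- Reduce(`+`, lapply(curves, function(cv) cv$table$TP))
  fp <- Reduce(`+`, lapply(curves, function(cv) cv$table$FP))
  fn <- Reduce(`+`, lapply(curves, function(cv) cv$table$FN))
  rows <- lapply(seq_along(scales), function(i) {
    pr <- precision_recall(list(TP = tp[i], FP = fp[i], FN = fn[i]))
    data.frame(scale = scales[i], TP = tp[i], FP = fp[i], FN = fn[i],
               precision = pr$precision, recall = pr$recall, f1 = pr$f1,
               n_detected = tp[i] + fp[i])
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 best_scale = tab$scale[which.max(tab$f1)],
                 best_f1 = max(tab$f1),
                 degenerate = all(tab$n_detected == 0),
                 threshold = NA_real_),
            class = "pr_curve")
}

#' Subthreshold optical-electrical correspondence
#'
#' Both traces are low-pass filtered at 50 Hz (spikes are not excluded),
#' the fluorescence is linearly interpolated to the electrophysiology
#' sampling rate, the paired samples are binned into a 150 x 150 joint
#' histogram normalized to a probability distribution, and a linear
#' regression quantifies the optical gain in dF/F per mV.
#'
#' @param ephys a `vs_voltage` or a `vs_trace` of membrane potential (mV).
#' @param dff a `vs_trace` of dF/F at the imaging rate.
#' @param nbins histogram bins per axis (default 150).
#' @param lowpass_hz common low-pass cutoff (default 50).
#' @return list with `hist2d` (probability matrix, voltage x dF/F),
#'   `v_breaks`, `f_breaks`, `slope` (dF/F per mV), `intercept` and
#'   `undefined` flag (constant voltage).
#' @export
subthreshold_correspondence <- function(ephys, dff, nbins = 150,
                                        lowpass_hz = 50) {
  if (inherits(ephys, "vs_voltage"))
    ephys <- vs_trace(ephys$v_mV, ephys$sim_rate, "mV")
  stopifnot(inherits(ephys, "vs_trace"), inherits(dff, "vs_trace"))
  v <- butter_filter(ephys$values, ephys$rate, lowpass_hz, "low",
                     order = 2, zero_phase = TRUE)
  f <- butter_filter(dff$values, dff$rate, min(lowpass_hz,
                                               dff$rate / 2 * 0.9), "low",
                     order = 2, zero_phase = TRUE)
  fi <- stats::approx(trace_time(dff), f, xout = trace_time(ephys),
                      rule = 2)$y
  if (stats::sd(v) == 0)
    return(list(hist2d = NULL, slope = NA_real_, intercept = NA_real_,
                undefined = TRUE))
  v_breaks <- seq(min(v), max(v), length.out = nbins + 1)
  f_breaks <- seq(min(fi), max(fi), length.out = nbins + 1)
  vb <- pmin(pmax(findInterval(v, v_breaks, rightmost.closed = TRUE),
                  1), nbins)
  fb <- pmin(pmax(findInterval(fi, f_breaks, rightmost.closed = TRUE),
                  1), nbins)
  h <- matrix(0, nbins, nbins)
  tab <- table(factor(vb, levels = seq_len(nbins)),
               factor(fb, levels = seq_len(nbins)))
  h[] <- as.numeric(tab)
  h <- h / sum(h)
  fit <- stats::lm(fi ~ v)
  list(hist2d = h, v_breaks = v_breaks, f_breaks = f_breaks,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), undefined = FALSE)
}
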