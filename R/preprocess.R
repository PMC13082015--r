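#' @title Movie and trace preprocessing
#' @description Background estimation, two-step motion correction,
#'   correlation-based pixel selection, photobleach fitting/correction and
#'   the dF/F baseline conventions used across acquisition modalities.
#' @name preprocess
NULL

#' Pixels saturated at any point of a movie
#' @param movie a `vs_movie`.
#' @return logical matrix, `TRUE` where a pixel reaches the saturation
#'   ceiling in any frame.
#' @export
saturated_mask <- function(movie) {
  stopifnot(inherits(movie, "vs_movie"))
  apply(movie$data >= movie$saturation, c(2, 3), any)
}

#' Estimate the background intensity of a movie
#'
#' Background is the mode of the first frame's pixel-intensity histogram,
#' excluding saturated pixels. Count-like (integer-valued) data use unit
#' bins; continuous data use Freedman-Diaconis bins.
#'
#' @param movie a `vs_movie`.
#' @return scalar background intensity (the mode bin value).
#' @export
estimate_background <- function(movie) {
  stopifnot(inherits(movie, "vs_movie"))
  px <- movie$data[1, , ]
  sat <- saturated_mask(movie)
  px <- px[!sat]
  if (length(px) == 0)
    stop("data error: all pixels saturated in the first frame",
         call. = FALSE)
  if (all(px == round(px))) {
    tab <- table(px)
    as.numeric(names(tab)[which.max(tab)])
  } else {
    h <- graphics::hist(px, breaks = "FD", plot = FALSE)
    h$mids[which.max(h$counts)]
  }
}

#' Subtract background from a movie
#' @param movie a `vs_movie`.
#' @param background scalar; defaults to [estimate_background()].
#' @param clamp clamp negative intensities at zero.
#' @return a background-corrected `vs_movie`.
#' @export
subtract_background <- function(movie, background = NULL, clamp = FALSE) {
  if (is.null(background)) background <- estimate_background(movie)
  d <- movie$data - background
  if (clamp) d[d < 0] <- 0
  vs_movie(d, movie$rate, movie$saturation)
}

# ---- motion correction ------------------------------------------------------

# Phase correlation between template `a` and frame `b`. Returns the (dx, dy)
# shift such that `b` is approximately `a` translated by (dx, dy)
# (dx = columns, dy = rows), with 3x3 centroid subpixel refinement.
phase_corr_shift <- function(a, b, subpixel = TRUE) {
  if (stats::sd(b) == 0 || stats::sd(a) == 0)
    return(c(dx = 0, dy = 0, degenerate = 1))
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  cp <- Fb * Conj(Fa)
  mag <- Mod(cp)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(stats::fft(cp / mag, inverse = TRUE))
  nr <- nrow(r); nc <- ncol(r)
  pk <- arrayInd(which.max(r), dim(r))
  py <- pk[1]; px <- pk[2]
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  dy <- wrap(py - 1, nr)
  dx <- wrap(px - 1, nc)
  if (subpixel) {
    idx <- function(i, n) ((i - 1) %% n) + 1
    nb <- outer(-1:1, -1:1, function(i, j)
      r[cbind(idx(py + i, nr), idx(px + j, nc))])
    nb <- nb - min(nb)
    if (sum(nb) > 0) {
      dy <- dy + sum((-1:1) * rowSums(nb)) / sum(nb)
      dx <- dx + sum((-1:1) * colSums(nb)) / sum(nb)
    }
  }
  c(dx = dx, dy = dy, degenerate = 0)
}

# Bilinear translation of a matrix by a possibly fractional shift,
# replicating edge values.
bilinear_shift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  y <- pmin(pmax(seq_len(nr) - dy, 1), nr)
  x <- pmin(pmax(seq_len(nc) - dx, 1), nc)
  y0 <- floor(y); y1 <- pmin(y0 + 1, nr); fy <- y - y0
  x0 <- floor(x); x1 <- pmin(x0 + 1, nc); fx <- x - x0
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wfy <- matrix(fy, nr, nc); wfx <- matrix(fx, nr, nc, byrow = TRUE)
  m00 * (1 - wfy) * (1 - wfx) + m01 * (1 - wfy) * wfx +
    m10 * wfy * (1 - wfx) + m11 * wfy * wfx
}

#' Two-step rigid motion correction by phase correlation
#'
#' Stage one estimates integer frame shifts against the global average
#' template and removes them. Stage two refines against a local rolling
#' template (window `local_window_s` seconds) with subpixel (3x3 centroid)
#' phase correlation. Frames are shifted by the inverse of the estimate.
#'
#' @param movie a `vs_movie` with at least two frames.
#' @param local_window_s local-template window in seconds (`NULL` skips the
#'   local stage).
#' @param pixel_size_um pixel pitch used only to express mean motion in
#'   micrometres for the exclusion flag.
#' @param max_motion_um recordings whose mean absolute shift exceeds this
#'   are flagged for exclusion.
#' @return a list with `movie` (corrected), `shifts` (data frame of
#'   per-frame dx, dy in pixels, total over both stages), `mean_shift_px`,
#'   `mean_shift_um`, `excluded` and `degenerate` flags.
#' @export
motion_correct <- function(movie, local_window_s = NULL,
                           pixel_size_um = 1, max_motion_um = 10) {
  stopifnot(inherits(movie, "vs_movie"), dim(movie$data)[1] >= 2)
  d <- movie$data
  n <- dim(d)[1]
  degenerate <- FALSE
  sh <- matrix(0, n, 2)
  # two passes: the first template is blurred by the motion itself, so a
  # second estimation against the sharpened post-correction template
  # resolves residual one-pixel errors
  for (pass in 1:2) {
    template <- apply(d, c(2, 3), mean)
    res <- matrix(0, n, 2)
    for (f in seq_len(n)) {
      s <- phase_corr_shift(template, d[f, , ], subpixel = FALSE)
      if (s[["degenerate"]] == 1) degenerate <- TRUE
      res[f, ] <- round(c(s[["dx"]], s[["dy"]]))
    }
    # the template carries an arbitrary common displacement; re-center the
    # shift table on its median so the reference is the dominant position
    res <- sweep(res, 2, round(apply(res, 2, stats::median)))
    for (f in seq_len(n)) {
      if (any(res[f, ] != 0))
        d[f, , ] <- shift_matrix(d[f, , ], -res[f, 2], -res[f, 1],
                                 fill = stats::median(d[f, , ]))
    }
    sh <- sh + res
    if (all(res == 0)) break
  }
  sh2 <- matrix(0, n, 2)
  if (!is.null(local_window_s)) {
    w <- max(1L, round(local_window_s * movie$rate))
    half <- w %/% 2
    flat <- matrix(d, nrow = n)
    cum <- apply(flat, 2, cumsum)
    for (f in seq_len(n)) {
      lo <- max(1, f - half); hi <- min(n, f + half)
      tmpl_vec <- (cum[hi, ] - (if (lo > 1) cum[lo - 1, ] else 0)) /
        (hi - lo + 1)
      tmpl <- matrix(tmpl_vec, dim(d)[2], dim(d)[3])
      s <- phase_corr_shift(tmpl, d[f, , ], subpixel = TRUE)
      sh2[f, ] <- c(s[["dx"]], s[["dy"]])
      if (any(abs(sh2[f, ]) > 1e-3))
        d[f, , ] <- bilinear_shift(d[f, , ], -sh2[f, 2], -sh2[f, 1])
    }
  }
  total <- sh + sh2
  mean_px <- mean(sqrt(rowSums(total^2)))
  list(movie = vs_movie(d, movie$rate, movie$saturation),
       shifts = data.frame(dx = total[, 1], dy = total[, 2]),
       mean_shift_px = mean_px,
       mean_shift_um = mean_px * pixel_size_um,
       excluded = mean_px * pixel_size_um > max_motion_um,
       degenerate = degenerate)
}

# ---- pixel selection --------------------------------------------------------

#' Correlation-ranked pixel selection maximizing summed-trace SNR
#'
#' A template trace (mean over the foreground mask) is correlated with every
#' masked pixel's trace (Pearson r); pixels are ranked by r and the prefix
#' of the ranking whose summed trace maximizes the SNR is selected. SNR is
#' (peak of summed trace - baseline mean) / baseline SD with the baseline
#' taken as the first `baseline_s` seconds. Selections smaller than
#' `min_pixels` reject the field of view.
#'
#' @param movie a background-corrected `vs_movie`.
#' @param mask logical foreground matrix.
#' @param min_pixels minimum surviving selection size (default 300).
#' @param baseline_s baseline window (s) used in the SNR definition.
#' @return a list with `ranked` (pixel indices into the mask, by r),
#'   `snr_curve` (per-prefix SNR), `chosen` (prefix length), `selected`
#'   (logical matrix) and `rejected` flag.
#' @export
select_pixels <- function(movie, mask, min_pixels = 300, baseline_s = 0.1) {
  stopifnot(inherits(movie, "vs_movie"), any(mask))
  d <- dim(movie$data)
  flat <- matrix(movie$data, nrow = d[1])   # frames x pixels
  pix_idx <- which(as.vector(mask))
  traces <- flat[, pix_idx, drop = FALSE]
  template <- rowMeans(traces)
  if (stats::sd(template) == 0)
    stop("selection error: zero-variance template", call. = FALSE)
  r <- suppressWarnings(as.numeric(stats::cor(traces, template)))
  r[is.na(r)] <- -Inf
  ord <- order(r, decreasing = TRUE)
  cumtr <- apply(traces[, ord, drop = FALSE], 1, cumsum)
  # cumtr is prefixes x frames
  nb <- max(2L, round(baseline_s * movie$rate))
  bl <- cumtr[, seq_len(nb), drop = FALSE]
  bl_mean <- rowMeans(bl)
  bl_sd <- apply(bl, 1, stats::sd)
  pk <- apply(cumtr, 1, max)
  snr <- (pk - bl_mean) / bl_sd
  snr[!is.finite(snr)] <- -Inf
  chosen <- which.max(snr)
  selected <- matrix(FALSE, d[2], d[3])
  selected[pix_idx[ord[seq_len(chosen)]]] <- TRUE
  list(ranked = pix_idx[ord], r = r[ord], snr_curve = snr,
       chosen = chosen, selected = selected,
       rejected = chosen < min_pixels, min_pixels = min_pixels)
}

# ---- photobleach fitting ----------------------------------------------------

exp_model_fn <- function(order) {
  function(t, pars) {
    out <- rep(pars[["c0"]], length(t))
    for (i in seq_len(order))
      out <- out + pars[[paste0("a", i)]] *
        exp(-t / pars[[paste0("tau", i)]])
    out
  }
}

fit_exp_order <- function(t, y, order) {
  # tau initialization from a log-linear fit on the tail decay
  y0 <- y - min(y) + 1e-12 * max(abs(y), 1)
  span <- t[length(t)] - t[1]
  tau0 <- tryCatch({
    pos <- y0 > max(y0) * 0.05
    fit <- stats::lm(log(y0[pos]) ~ t[pos])
    tau <- -1 / stats::coef(fit)[2]
    if (!is.finite(tau) || tau <= 0) span / 3 else tau
  }, error = function(e) span / 3)
  amp0 <- (y[1] - y[length(y)]) / order
  form_terms <- paste(sprintf("a%d * exp(-t / tau%d)", seq_len(order),
                              seq_len(order)), collapse = " + ")
  form <- stats::as.formula(paste("y ~", form_terms, "+ c0"))
  lower <- c(rep(-Inf, order), rep(1e-9, order), -Inf)
  fit <- NULL
  # a collapsed pair of taus makes the Jacobian singular; retry with
  # increasingly spread initial time constants
  for (spread in c(3, 10, 30)) {
    taus <- tau0 * spread^(seq_len(order) - (order + 1) / 2)
    start <- c(stats::setNames(rep(amp0, order),
                               paste0("a", seq_len(order))),
               stats::setNames(taus, paste0("tau", seq_len(order))),
               c0 = y[length(y)])
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(t = t, y = y),
                        start = as.list(start), lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(NULL)
  pars <- as.list(stats::coef(fit))
  res <- y - exp_model_fn(order)(t, pars)
  n <- length(y)
  rss <- sum(res^2)
  k <- 2 * order + 1
  list(order = order, pars = pars,
       amplitudes = unname(unlist(pars[paste0("a", seq_len(order))])),
       taus_s = unname(unlist(pars[paste0("tau", seq_len(order))])),
       offset = pars$c0,
       r2 = 1 - rss / sum((y - mean(y))^2),
       rmse = sqrt(rss / n), mae = mean(abs(res)),
       aic = n * log(rss / n) + 2 * (k + 1),
       bic = n * log(rss / n) + log(n) * (k + 1))
}

#' Fit a multi-exponential photobleach model with AIC/BIC-guarded selection
#'
#' Fits single, double and triple exponential-plus-offset decay models to a
#' trace (after removing excluded intervals). The reported model is the one
#' with the highest R-squared (ties broken by RMSE then MAE) among orders at
#' which both BIC and AIC are at a local minimum across the fitted orders;
#' this guards against overfitting.
#'
#' @param trace a `vs_trace`.
#' @param exclude_intervals list of `c(start_s, end_s)` intervals (e.g.
#'   stimulation epochs) removed before fitting.
#' @param orders exponential orders to try.
#' @return a `bleach_fit` list: chosen `model_order`, `amplitudes`,
#'   `taus_s`, `offset`, per-order fit statistics and a `predict(t)`
#'   function.
#' @export
fit_bleach <- function(trace, exclude_intervals = NULL, orders = 1:3) {
  stopifnot(inherits(trace, "vs_trace"))
  t <- trace_time(trace)
  y <- trace$values
  if (!is.null(exclude_intervals)) {
    keep <- rep(TRUE, length(t))
    for (iv in exclude_intervals) keep <- keep & !(t >= iv[1] & t <= iv[2])
    t <- t[keep]; y <- y[keep]
  }
  stopifnot(length(y) >= 10 * (2 * max(orders) + 1))
  if (stats::sd(y) < 1e-12 * max(abs(mean(y)), 1)) {
    fits <- list()
    pars <- list(a1 = 0, tau1 = 1, c = mean(y))
    return(structure(list(model_order = 1, amplitudes = 0, taus_s = 1,
                          offset = mean(y), stats = NULL,
                          predict = function(tt) rep(mean(y), length(tt))),
                     class = "bleach_fit"))
  }
  fits <- lapply(orders, function(o) fit_exp_order(t, y, o))
  names(fits) <- paste0("order", orders)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("fit error: no exponential order converged", call. = FALSE)
  stat <- do.call(rbind, lapply(fits[ok], function(f)
    data.frame(order = f$order, r2 = f$r2, rmse = f$rmse, mae = f$mae,
               aic = f$aic, bic = f$bic)))
  # local-minimum rule across adjacent fitted orders
  is_local_min <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
      lo <- if (i > 1) v[i] < v[i - 1] else TRUE
      hi <- if (i < n) v[i] < v[i + 1] else TRUE
      lo && hi
    }, logical(1))
  }
  admissible <- is_local_min(stat$aic) & is_local_min(stat$bic)
  if (!any(admissible)) admissible <- rep(TRUE, nrow(stat))
  cand <- stat[admissible, ]
  cand <- cand[order(-cand$r2, cand$rmse, cand$mae), ]
  best <- fits[[paste0("order", cand$order[1])]]
  fn <- exp_model_fn(best$order)
  pars <- best$pars
  structure(list(model_order = best$order, amplitudes = best$amplitudes,
                 taus_s = best$taus_s, offset = best$offset, stats = stat,
                 predict = function(tt) fn(tt, pars)),
            class = "bleach_fit")
}

#' Divide out a fitted bleach curve
#'
#' The fitted curve is normalized to 1 at t = 0 and the trace divided by it.
#'
#' @param trace a `vs_trace`.
#' @param fit a `bleach_fit` from [fit_bleach()].
#' @return a corrected `vs_trace`.
#' @export
bleach_correct <- function(trace, fit) {
  stopifnot(inherits(trace, "vs_trace"), inherits(fit, "bleach_fit"))
  f0 <- fit$predict(0)
  env <- fit$predict(trace_time(trace)) / f0
  vs_trace(trace$values / env, trace$rate, trace$units)
}

# ---- dF/F baselines ---------------------------------------------------------

#' Convert a fluorescence trace to dF/F under a named baseline convention
#'
#' * `rolling_p5`: F0 is the bottom 5th percentile of fluorescence over
#'   rolling windows (`window_s`, default 30 s).
#' * `mean`: F0 is the mean over `params$window_s = c(start, end)` (default:
#'   the whole trace).
#' * `blank_window`: F0 is, per stimulation cycle, the mean over the 0.3 to
#'   0.5 s span of the blank period preceding each stimulus
#'   (`params$blank_onsets_s`).
#' * `lowpass_divide`: the trace is detrended by subtracting a low-pass
#'   (default 0.1 Hz) filtered copy and dividing by it.
#'
#' @param trace a `vs_trace` of fluorescence (must be positive where a
#'   baseline is formed).
#' @param method baseline convention.
#' @param params method parameters (see above).
#' @return a `vs_trace` of dF/F.
#' @export
compute_dff <- function(trace,
                        method = c("rolling_p5", "mean", "blank_window",
                                   "lowpass_divide"),
                        params = list()) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "vs_trace"))
  y <- trace$values
  if (stats::sd(y) == 0) {
    if (y[1] <= 0) stop("baseline error: F0 <= 0", call. = FALSE)
    return(vs_trace(rep(0, length(y)), trace$rate, "dff"))
  }
  t <- trace_time(trace)
  f0 <- switch(method,
    rolling_p5 = {
      window_s <- if (!is.null(params$window_s)) params$window_s else 30
      w <- max(2L, round(window_s * trace$rate))
      step <- max(1L, w %/% 20)
      rolling_quantile(y, w, 0.05, step = step)
    },
    mean = {
      win <- params$window_s
      if (is.null(win)) mean(y) else
        mean(y[t >= win[1] & t <= win[2]])
    },
    blank_window = {
      on <- params$blank_onsets_s
      stopifnot(!is.null(on))
      f0v <- numeric(length(y))
      bounds <- c(on, Inf)
      for (i in seq_along(on)) {
        in_bl <- t >= on[i] + 0.3 & t <= on[i] + 0.5
        seg <- t >= on[i] & t < bounds[i + 1]
        f0v[seg] <- mean(y[in_bl])
      }
      f0v[t < on[1]] <- f0v[which(t >= on[1])[1]]
      f0v
    },
    lowpass_divide = {
      cutoff <- if (!is.null(params$cutoff_hz)) params$cutoff_hz else 0.1
      butter_filter(y, trace$rate, cutoff, "low", order = 2,
                    zero_phase = TRUE)
    })
  if (any(f0 <= 0)) stop("baseline error: F0 <= 0", call. = FALSE)
  vs_trace((y - f0) / f0, trace$rate, "dff")
}

#' Power-law slope of the late photobleaching phase
#'
#' The trace is low-pass filtered (default 1 Hz), downsampled (default 140
#' times), restricted to `t >= t_start_s`, and a line is fitted to
#' log10(F) vs log10(t); the slope of that line is returned.
#'
#' @param trace a `vs_trace`.
#' @param t_start_s start of the late phase (default 60 s).
#' @param lowpass_hz low-pass cutoff before downsampling (skipped when the
#'   rate is too low to support it).
#' @param downsample decimation factor.
#' @return scalar power-law slope.
#' @export
bleach_power_law <- function(trace, t_start_s = 60, lowpass_hz = 1,
                             downsample = 140) {
  stopifnot(inherits(trace, "vs_trace"))
  y <- trace$values
  if (length(y) / trace$rate <= t_start_s)
    stop("trace shorter than t_start_s", call. = FALSE)
  if (stats::sd(y) == 0) return(0)
  if (lowpass_hz < trace$rate / 2)
    y <- butter_filter(y, trace$rate, lowpass_hz, "low", order = 2)
  ds <- max(1L, as.integer(min(downsample, floor(length(y) / 20))))
  idx <- seq(1L, length(y), by = ds)
  t <- trace_time(trace)[idx]
  y <- y[idx]
  keep <- t >= t_start_s
  t <- t[keep]; y <- y[keep]
  if (any(y <= 0))
    stop("domain error: non-positive values after conditioning",
         call. = FALSE)
  unname(stats::coef(stats::lm(log10(y) ~ log10(t)))[2])
}

#' Quadratic illumination-power correction of a spectrum
#'
#' Fluorescence under two-photon excitation scales with the square of the
#' illumination power, so values measured at power `P` are rescaled by
#' `(P_ref / P)^2` before optional normalization to the spectrum maximum.
#'
#' @param values fluorescence per wavelength.
#' @param powers measured power per wavelength (> 0).
#' @param p_ref reference power (default: the first entry of `powers`).
#' @param normalize divide the corrected spectrum by its maximum.
#' @return corrected (optionally normalized) spectrum.
#' @export
power_correct <- function(values, powers, p_ref = powers[1],
                          normalize = TRUE) {
  stopifnot(length(values) == length(powers))
  if (any(powers <= 0)) stop("domain error: zero power", call. = FALSE)
  out <- values * (p_ref / powers)^2
  if (normalize) out <- out / max(out)
  out
}
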