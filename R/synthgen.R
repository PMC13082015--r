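#' @title Synthetic GEVI data generation
#' @description Generators for membrane voltage, indicator fluorescence,
#'   photon counts, movies and population datasets with exact ground truth.
#'   Every generator threads a single integer seed through an isolated RNG
#'   so repeated calls are bitwise-reproducible and do not disturb the
#'   session RNG state.
#' @name synthgen
NULL

# Run `expr` under a private RNG seeded with `seed`; restore global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- action-potential template ---------------------------------------------

# Gaussian AP shape with exact amplitude and FWHM. Action potentials
# repolarize quickly; a heavy-tailed shape would let the voltage tail,
# amplified by the steep sigmoid above rest, dominate the optical spike
# width.
ap_template <- function(fwhm_ms, amplitude_mV, sim_rate) {
  sigma <- fwhm_ms / 1000 / (2 * sqrt(2 * log(2)))
  n_half <- ceiling(3.5 * sigma * sim_rate)
  t <- (-n_half:n_half) / sim_rate     # grid centered on the peak
  w <- amplitude_mV * exp(-t^2 / (2 * sigma^2))
  peak_offset <- which.max(w) - 1L   # samples from onset to peak
  list(wave = w, peak_offset = peak_offset)
}

add_spikes <- function(v, spike_times_s, sim_rate, fwhm_ms, amplitude_mV) {
  if (length(spike_times_s) == 0) return(v)
  tmpl <- ap_template(fwhm_ms, amplitude_mV, sim_rate)
  for (ts in spike_times_s) {
    # spike_times mark the peak; place the template so its peak lands there
    i0 <- round(ts * sim_rate) - tmpl$peak_offset + 1L
    idx <- seq.int(i0, length.out = length(tmpl$wave))
    ok <- idx >= 1 & idx <= length(v)
    v[idx[ok]] <- v[idx[ok]] + tmpl$wave[ok]
  }
  v
}

# ---- voltage simulation -----------------------------------------------------

#' Simulate a membrane-voltage recording with ground-truth spike times
#'
#' Four protocols are supported. `"steps"` reproduces a voltage-clamp
#' command series: a 4-s hold at the holding potential followed by 1-s steps
#' to each level in `step_levels_mV`, each separated by 1 s back at hold.
#' `"spike_train"` superimposes stereotyped action-potential waveforms
#' (default 100 mV amplitude, 2 ms FWHM) on the holding potential.
#' `"burst_on_up_state"` places a burst of spikes on a sustained subthreshold
#' depolarization plateau (default ~24 mV). `"spontaneous"` draws spike times
#' from a Poisson process with a refractory minimum gap and adds
#' Ornstein-Uhlenbeck subthreshold fluctuations.
#'
#' @param protocol one of `"steps"`, `"spike_train"`, `"burst_on_up_state"`,
#'   `"spontaneous"`.
#' @param duration_s recording length (ignored for `"steps"`, which is sized
#'   by its step table).
#' @param sim_rate simulation rate in Hz; must be at least 2000.
#' @param seed integer seed for all random draws.
#' @param hold_mV holding / resting potential.
#' @param step_levels_mV step levels for the `"steps"` protocol.
#' @param n_spikes,spike_rate_hz number and rate of evoked spikes
#'   (`"spike_train"` / `"burst_on_up_state"`).
#' @param fwhm_ms,amplitude_mV action-potential width and height.
#' @param rate_hz mean spontaneous firing rate (`"spontaneous"`).
#' @param refractory_s minimum gap between spontaneous spikes.
#' @param ou_tau_s,ou_sigma_mV Ornstein-Uhlenbeck time constant and
#'   stationary SD of the subthreshold fluctuation (0 disables it).
#' @param up_mV,up_duration_s plateau height and length for
#'   `"burst_on_up_state"`.
#' @param noise_sd_mV white measurement noise added to the trace.
#' @return a `vs_voltage` list with `time_s`, `v_mV`, `spike_times_s`,
#'   `up_state_intervals`, `sim_rate` and, for `"steps"`, a `steps` table.
#' @export
simulate_voltage <- function(protocol = c("steps", "spike_train",
                                          "burst_on_up_state", "spontaneous"),
                             duration_s = 10, sim_rate = 10000, seed = 1,
                             hold_mV = -70,
                             step_levels_mV = c(90, 70, 50, 30, 20, 0, -20,
                                                -40, -60, -80, -100, -120),
                             n_spikes = 5, spike_rate_hz = 2,
                             fwhm_ms = 2, amplitude_mV = 100,
                             rate_hz = 5, refractory_s = 0.005,
                             ou_tau_s = 0.05, ou_sigma_mV = 0,
                             up_mV = 24, up_duration_s = 0.5,
                             noise_sd_mV = 0) {
  protocol <- tryCatch(match.arg(protocol),
                       error = function(e) stop("unknown protocol name",
                                                call. = FALSE))
  if (sim_rate < 2000) stop("sim_rate too low: need >= 2 kHz", call. = FALSE)
  spike_times <- numeric(0)
  up_intervals <- list()
  steps <- NULL

  if (protocol == "steps") {
    hold_pre <- 4
    duration_s <- hold_pre + 2 * length(step_levels_mV)
    n <- round(duration_s * sim_rate)
    v <- rep(hold_mV, n)
    onsets <- hold_pre + 2 * (seq_along(step_levels_mV) - 1)
    for (i in seq_along(step_levels_mV)) {
      i0 <- round(onsets[i] * sim_rate) + 1L
      i1 <- round((onsets[i] + 1) * sim_rate)
      v[i0:i1] <- step_levels_mV[i]
    }
    steps <- data.frame(level_mV = step_levels_mV, onset_s = onsets,
                        offset_s = onsets + 1)
  } else if (protocol == "spike_train") {
    period <- 1 / spike_rate_hz
    spike_times <- if (n_spikes > 0) 0.5 + period * (seq_len(n_spikes) - 1)
                   else numeric(0)
    duration_s <- max(duration_s,
                      if (n_spikes > 0) max(spike_times) + 0.5 else 1)
    n <- round(duration_s * sim_rate)
    v <- rep(hold_mV, n)
    v <- add_spikes(v, spike_times, sim_rate, fwhm_ms, amplitude_mV)
  } else if (protocol == "burst_on_up_state") {
    n <- round(duration_s * sim_rate)
    v <- rep(hold_mV, n)
    up_start <- duration_s / 2 - up_duration_s / 2
    up_intervals <- list(c(up_start, up_start + up_duration_s))
    t <- (seq_len(n) - 0.5) / sim_rate
    # smooth plateau edges with a 10-ms exponential shoulder
    edge <- 0.01
    plateau <- up_mV * (1 - exp(-pmax(0, t - up_start) / edge)) *
      exp(-pmax(0, t - (up_start + up_duration_s)) / edge)
    v <- v + plateau
    spike_times <- with_seed(seed, {
      ts <- up_start + 0.05 + (seq_len(n_spikes) - 1) / spike_rate_hz
      ts[ts < up_start + up_duration_s - 0.01]
    })
    amps <- seq(60, 90, length.out = max(length(spike_times), 1))
    for (i in seq_along(spike_times))
      v <- add_spikes(v, spike_times[i], sim_rate,
                      fwhm_ms = stats::runif(1, 1.5, 2), amps[i])
  } else { # spontaneous
    n <- round(duration_s * sim_rate)
    v <- rep(hold_mV, n)
    gen <- with_seed(seed, {
      ts <- numeric(0)
      if (rate_hz > 0) {
        t <- 0
        repeat {
          t <- t + refractory_s + stats::rexp(1, rate_hz)
          if (t > duration_s - 0.02) break
          ts <- c(ts, t)
        }
      }
      ou <- numeric(n)
      if (ou_sigma_mV > 0) {
        a <- exp(-1 / (sim_rate * ou_tau_s))
        innov <- stats::rnorm(n, 0, ou_sigma_mV * sqrt(1 - a^2))
        ou <- as.numeric(stats::filter(innov, a, method = "recursive"))
      }
      wn <- if (noise_sd_mV > 0) stats::rnorm(n, 0, noise_sd_mV) else 0
      list(ts = ts, ou = ou, wn = wn)
    })
    spike_times <- gen$ts
    v <- v + gen$ou + gen$wn
    v <- add_spikes(v, spike_times, sim_rate, fwhm_ms, amplitude_mV)
  }

  if (noise_sd_mV > 0 && protocol != "spontaneous")
    v <- v + with_seed(seed + 1L, stats::rnorm(length(v), 0, noise_sd_mV))

  stopifnot(all(is.finite(v)),
            length(spike_times) < 2 || all(diff(spike_times) > 0))
  structure(list(time_s = (seq_along(v) - 0.5) / sim_rate, v_mV = v,
                 spike_times_s = spike_times,
                 up_state_intervals = up_intervals,
                 sim_rate = sim_rate, steps = steps),
            class = "vs_voltage")
}

#' @export
print.vs_voltage <- function(x, ...) {
  cat(sprintf("<vs_voltage> %.2f s @ %g Hz, %d spikes\n",
              length(x$v_mV) / x$sim_rate, x$sim_rate,
              length(x$spike_times_s)))
  invisible(x)
}

# ---- indicator model --------------------------------------------------------

#' Indicator fluorescence-voltage model
#'
#' Describes a voltage indicator by its steady-state sigmoid
#' \eqn{F(v) = L / (1 + e^{-k (v - x_0)}) + b} (dF/F vs mV), direction-
#' dependent multi-exponential on/off kinetics, a baseline photon flux, and a
#' multi-exponential photobleaching envelope. The default parameters describe
#' a positive-going sensor anchored so that dF/F is 0 at -70 mV, 0.874 at
#' -40 mV and 2.27 at 0 mV, with on kinetics of 2.8 ms and off kinetics of
#' 2.4 and 9.1 ms at equal weight. These defaults are a realistic fixture for
#' testing the analysis chain, not a characterization claim.
#'
#' @param L,k_slope,x0,b sigmoid parameters; if `NULL` they are solved so the
#'   anchored curve passes through `anchors` (with `x0` fixed at
#'   `x0_default`).
#' @param anchors data frame with columns `mV`, `dff` used to anchor the
#'   default sigmoid (relative to a -70 mV baseline).
#' @param x0_default inflection voltage used when solving the default curve.
#' @param tau_on_ms,tau_off_ms data frames with columns `tau_ms`, `weight`;
#'   weights must sum to 1 per direction.
#' @param flux baseline photon flux (photons/s) at dF/F = 0.
#' @param bleach data frame with columns `amplitude`, `tau_s`; the bleaching
#'   envelope is `sum(a_i exp(-t/tau_i)) + (1 - sum(a_i))`, so it equals 1 at
#'   t = 0. `NULL` disables bleaching.
#' @return an object of class `gevi_model`.
#' @export
gevi_model <- function(L = NULL, k_slope = NULL, x0 = NULL, b = NULL,
                       anchors = data.frame(mV = c(-40, 0),
                                            dff = c(0.874, 2.27)),
                       x0_default = -25,
                       tau_on_ms = data.frame(tau_ms = 2.8, weight = 1),
                       tau_off_ms = data.frame(tau_ms = c(2.4, 9.1),
                                               weight = c(0.5, 0.5)),
                       flux = 1e5, bleach = NULL) {
  if (is.null(L) || is.null(k_slope) || is.null(x0) || is.null(b)) {
    stopifnot(nrow(anchors) == 2)
    sig <- function(v, k) 1 / (1 + exp(-k * (v - x0_default)))
    ratio <- anchors$dff[2] / anchors$dff[1]
    froot <- function(k) (sig(anchors$mV[2], k) - sig(-70, k)) /
      (sig(anchors$mV[1], k) - sig(-70, k)) - ratio
    k_slope <- stats::uniroot(froot, c(1e-4, 1), tol = 1e-12)$root
    L <- anchors$dff[1] / (sig(anchors$mV[1], k_slope) - sig(-70, k_slope))
    x0 <- x0_default
    b <- -L * sig(-70, k_slope)   # anchor: F(-70) = 0
  }
  stopifnot(all(tau_on_ms$tau_ms > 0), all(tau_off_ms$tau_ms > 0),
            abs(sum(tau_on_ms$weight) - 1) < 1e-9,
            abs(sum(tau_off_ms$weight) - 1) < 1e-9,
            flux >= 0)
  if (!is.null(bleach)) stopifnot(all(bleach$tau_s > 0))
  structure(list(L = L, k_slope = k_slope, x0 = x0, b = b,
                 tau_on_ms = tau_on_ms, tau_off_ms = tau_off_ms,
                 flux = flux, bleach = bleach),
            class = "gevi_model")
}

#' Steady-state sigmoid of an indicator model
#' @param model a `gevi_model`.
#' @param v_mV voltages (mV).
#' @return steady-state dF/F at each voltage.
#' @export
model_sigmoid <- function(model, v_mV) {
  model$L / (1 + exp(-model$k_slope * (v_mV - model$x0))) + model$b
}

#' Local slope of the model sigmoid (dF/F per mV)
#' @inheritParams model_sigmoid
#' @export
model_sigmoid_slope <- function(model, v_mV) {
  s <- 1 / (1 + exp(-model$k_slope * (v_mV - model$x0)))
  model$L * model$k_slope * s * (1 - s)
}

# Bleaching envelope, 1 at t = 0.
bleach_envelope <- function(model, t_s) {
  if (is.null(model$bleach)) return(rep(1, length(t_s)))
  a <- model$bleach$amplitude
  tau <- model$bleach$tau_s
  out <- rep(1 - sum(a), length(t_s))
  for (i in seq_along(a)) out <- out + a[i] * exp(-t_s / tau[i])
  out
}

#' Convert a voltage trace to indicator dF/F
#'
#' The steady-state target at each instant is the model sigmoid of the
#' current voltage; the fluorescence relaxes towards it by exact exponential
#' update per simulation step (not an Euler approximation), using the on
#' kinetics when the target is above the current fluorescence and the off
#' kinetics otherwise. Multi-component kinetics evolve as independent states
#' with fixed weights; at a direction switch the newly active components are
#' re-initialized at the current total.
#'
#' @param v a `vs_voltage` from [simulate_voltage()].
#' @param model a [gevi_model()].
#' @return a `vs_trace` of dF/F at the simulation rate.
#' @export
voltage_to_dff <- function(v, model) {
  stopifnot(inherits(v, "vs_voltage"), inherits(model, "gevi_model"))
  S <- model_sigmoid(model, v$v_mV)
  dt <- 1 / v$sim_rate
  a_on <- exp(-dt / (model$tau_on_ms$tau_ms / 1000))
  a_off <- exp(-dt / (model$tau_off_ms$tau_ms / 1000))
  w_on <- model$tau_on_ms$weight
  w_off <- model$tau_off_ms$weight
  n <- length(S)
  out <- numeric(n)
  f_tot <- S[1]
  f_on <- rep(f_tot, length(a_on))
  f_off <- rep(f_tot, length(a_off))
  for (i in seq_len(n)) {
    s <- S[i]
    if (s >= f_tot) {
      f_on <- s + (f_on - s) * a_on
      f_tot <- sum(w_on * f_on)
      f_off[] <- f_tot
    } else {
      f_off <- s + (f_off - s) * a_off
      f_tot <- sum(w_off * f_off)
      f_on[] <- f_tot
    }
    out[i] <- f_tot
  }
  vs_trace(out, v$sim_rate, units = "dff")
}

#' Emit Poisson photon counts from a dF/F trace
#'
#' Integrates the dF/F trace over imaging frames and draws per-frame photon
#' counts from a Poisson law with mean
#' `flux * frame_dt * (1 + dFF) * bleach(t)`.
#'
#' @param dff a `vs_trace` of dF/F (rate at least `frame_rate`).
#' @param model a [gevi_model()] supplying `flux` and the bleach envelope.
#' @param frame_rate imaging frame rate in Hz.
#' @param seed integer seed.
#' @return a `vs_trace` of photon counts at `frame_rate`.
#' @export
emit_photons <- function(dff, model, frame_rate, seed = 1) {
  stopifnot(inherits(dff, "vs_trace"), frame_rate <= dff$rate)
  rel <- 1 + dff$values
  if (any(rel < 0))
    stop("model error: 1 + dF/F < 0 gives a negative photon rate",
         call. = FALSE)
  # assign each simulation sample to the frame covering its timestamp so
  # the output timebase is exact even when the rates are not commensurate
  t_s <- (seq_along(rel) - 0.5) / dff$rate
  frame <- floor(t_s * frame_rate) + 1L
  n_frames <- max(frame) - 1L     # drop the possibly partial last frame
  keep <- frame <= n_frames
  rel_frame <- as.numeric(
    rowsum(rel[keep], frame[keep]) / tabulate(frame[keep], n_frames))
  t_center <- (seq_len(n_frames) - 0.5) / frame_rate
  lambda <- model$flux / frame_rate * rel_frame *
    bleach_envelope(model, t_center)
  counts <- if (model$flux == 0) numeric(n_frames) else
    with_seed(seed, stats::rpois(n_frames, lambda))
  vs_trace(counts, frame_rate, units = "photons")
}

# ---- movie rendering --------------------------------------------------------

#' Specify a synthetic imaging scene
#'
#' @param nrow,ncol frame dimensions in pixels.
#' @param rate frame rate (Hz).
#' @param cells list of cells, each a list with `center` (row, col), `radius`
#'   (pixels), `flux` (expected photons/frame/pixel at dF/F = 0) and `dff`
#'   (per-frame dF/F vector).
#' @param n_frames number of frames (must match the cells' dff length).
#' @param neuropil_gain expected background photons/frame/pixel added
#'   everywhere.
#' @param motion integer `n_frames x 2` matrix of injected (dx, dy) shifts
#'   (columns, rows); `NULL` for a static scene.
#' @param poisson draw per-pixel Poisson noise (`FALSE` renders expected
#'   values).
#' @param seed integer seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(nrow, ncol, rate, cells, n_frames,
                       neuropil_gain = 0, motion = NULL, poisson = TRUE,
                       seed = 1) {
  if (is.null(motion)) motion <- matrix(0L, n_frames, 2)
  stopifnot(nrow(motion) == n_frames, ncol(motion) == 2)
  max_shift <- max(abs(motion))
  for (cl in cells) {
    stopifnot(length(cl$dff) == n_frames)
    if (cl$center[1] - cl$radius - max_shift < 1 ||
        cl$center[1] + cl$radius + max_shift > nrow ||
        cl$center[2] - cl$radius - max_shift < 1 ||
        cl$center[2] + cl$radius + max_shift > ncol)
      stop("scene error: cell overlaps the frame edge after maximal shift",
           call. = FALSE)
  }
  structure(list(nrow = nrow, ncol = ncol, rate = rate, cells = cells,
                 n_frames = n_frames, neuropil_gain = neuropil_gain,
                 motion = motion, poisson = poisson, seed = seed),
            class = "scene_spec")
}

disc_mask <- function(nrow, ncol, center, radius) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

shift_matrix <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Render a movie from a scene specification
#'
#' @param scene a [scene_spec()].
#' @return a list with `movie` (a `vs_movie`), `masks` (one logical matrix
#'   per cell, unshifted) and `truth` (injected shifts and per-cell dF/F).
#' @export
render_movie <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  masks <- lapply(scene$cells, function(cl)
    disc_mask(scene$nrow, scene$ncol, cl$center, cl$radius))
  base <- matrix(scene$neuropil_gain, scene$nrow, scene$ncol)
  arr <- array(0, dim = c(scene$n_frames, scene$nrow, scene$ncol))
  frames <- with_seed(scene$seed, {
    for (f in seq_len(scene$n_frames)) {
      img <- base
      for (i in seq_along(scene$cells)) {
        cl <- scene$cells[[i]]
        img[masks[[i]]] <- img[masks[[i]]] + cl$flux * (1 + cl$dff[f])
      }
      img <- shift_matrix(img, scene$motion[f, 2], scene$motion[f, 1],
                          fill = scene$neuropil_gain)
      if (scene$poisson)
        img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                      scene$nrow, scene$ncol)
      arr[f, , ] <- img
    }
    arr
  })
  list(movie = vs_movie(frames, scene$rate),
       masks = masks,
       truth = list(shifts = scene$motion,
                    dff = lapply(scene$cells, `[[`, "dff")))
}

# ---- population generators --------------------------------------------------

von_mises_gain <- function(theta_deg, pref_deg, kappa, period_deg = 180) {
  d <- (theta_deg - pref_deg) * 2 * pi / period_deg
  if (is.infinite(kappa))
    return(as.numeric(abs(((theta_deg - pref_deg) %% period_deg)) < 1e-9))
  exp(kappa * (cos(d) - 1))
}

#' Simulate stimulus-locked, multimodal, or open-field population datasets
#'
#' Three designs are available. `"grating_tuned"` emulates interleaved
#' drifting-grating trials (0.5-s blank, 0.5-s stimulus per presentation)
#' driving units with von Mises tuning; `"ach_coupled"` emulates a slow
#' (0.1-1 Hz) neuromodulator oscillation whose phase gates the amplitude of
#' 2-10 Hz voltage-band activity with an injected phase lag; `"arena_border"`
#' emulates open-field exploration of a square arena by a smoothed
#' random-walk trajectory with a border- (or center-) tuned Poisson spiking
#' unit.
#'
#' @param kind one of `"grating_tuned"`, `"ach_coupled"`, `"arena_border"`.
#' @param params named list of design parameters; see Details in the package
#'   vignette. Unset entries fall back to defaults.
#' @param seed integer seed.
#' @return a list with the generated dataset plus a `truth` element
#'   recording each unit's preferred direction, injected phase lag, or field
#'   geometry.
#' @export
simulate_population <- function(kind = c("grating_tuned", "ach_coupled",
                                         "arena_border"),
                                params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  switch(kind,
    grating_tuned = {
      n_units <- p("n_units", 8)
      directions <- p("directions", seq(0, 315, by = 45))
      n_trials <- p("n_trials", 10)
      frame_rate <- p("frame_rate", 100)
      blank_s <- p("blank_s", 0.5)
      stim_s <- p("stim_s", 0.5)
      kappa <- p("kappa", 4)
      amp <- p("amp", 1)
      noise_sd <- p("noise_sd", 0.05)
      tau_rise <- p("tau_rise", 0.1)
      period_deg <- p("period_deg", 180)
      prefs <- p("prefs",
                 with_seed(seed, stats::runif(n_units, 0, period_deg)))
      trial_dirs <- with_seed(seed + 1L,
                              sample(rep(directions, n_trials)))
      cycle <- blank_s + stim_s
      onset <- blank_s + cycle * (seq_along(trial_dirs) - 1)
      schedule <- data.frame(onset_s = onset, offset_s = onset + stim_s,
                             direction_deg = trial_dirs)
      duration <- cycle * length(trial_dirs) + blank_s
      n <- round(duration * frame_rate)
      t <- (seq_len(n) - 0.5) / frame_rate
      drive <- matrix(0, n, nrow(schedule))
      for (j in seq_len(nrow(schedule))) {
        r <- (1 - exp(-pmax(0, t - schedule$onset_s[j]) / tau_rise)) -
          (1 - exp(-pmax(0, t - schedule$offset_s[j]) / tau_rise))
        drive[, j] <- r
      }
      traces <- with_seed(seed + 2L, {
        m <- matrix(0, n, n_units)
        for (u in seq_len(n_units)) {
          g <- von_mises_gain(schedule$direction_deg, prefs[u], kappa,
                              period_deg)
          m[, u] <- amp * as.numeric(drive %*% g) +
            stats::rnorm(n, 0, noise_sd)
        }
        m
      })
      list(traces = traces, frame_rate = frame_rate, schedule = schedule,
           truth = list(pref_deg = prefs, kappa = kappa,
                        period_deg = period_deg))
    },
    ach_coupled = {
      duration_s <- p("duration_s", 120)
      frame_rate <- p("frame_rate", 100)
      f_mod <- p("f_mod_hz", 0.3)
      f_carrier <- p("f_carrier_hz", 5)
      lag_rad <- p("lag_rad", 0)
      depth <- p("depth", 0.8)
      noise_sd <- p("noise_sd", 0)
      n <- round(duration_s * frame_rate)
      t <- (seq_len(n) - 0.5) / frame_rate
      phase_mod <- 2 * pi * f_mod * t
      modulator <- cos(phase_mod)
      envelope <- 1 + depth * cos(phase_mod - lag_rad)
      nz <- with_seed(seed, if (noise_sd > 0)
        list(a = stats::rnorm(n, 0, noise_sd),
             b = stats::rnorm(n, 0, noise_sd)) else
        list(a = 0, b = 0))
      voltage <- envelope * sin(2 * pi * f_carrier * t) + nz$a
      list(voltage = vs_trace(voltage, frame_rate, "dff"),
           modulator = vs_trace(modulator + nz$b, frame_rate, "dff"),
           truth = list(lag_rad = lag_rad, f_mod_hz = f_mod,
                        f_carrier_hz = f_carrier, depth = depth))
    },
    arena_border = {
      duration_s <- p("duration_s", 600)
      frame_rate <- p("frame_rate", 30)
      arena_cm <- p("arena_cm", 80)
      field <- p("field", "border")  # "border" or "center"
      peak_rate <- p("peak_rate_hz", 8)
      base_rate <- p("base_rate_hz", 0.2)
      d0_cm <- p("d0_cm", 4)
      speed_sd <- p("speed_sd", 12)
      n <- round(duration_s * frame_rate)
      dt <- 1 / frame_rate
      sim <- with_seed(seed, {
        # OU velocity reflected at the walls
        vx <- vy <- 0
        x <- y <- arena_cm / 2
        xs <- ys <- numeric(n)
        a <- exp(-dt / 1)       # 1-s velocity correlation
        sv <- speed_sd * sqrt(1 - a^2)
        for (i in seq_len(n)) {
          vx <- a * vx + stats::rnorm(1, 0, sv)
          vy <- a * vy + stats::rnorm(1, 0, sv)
          x <- x + vx * dt; y <- y + vy * dt
          if (x < 0) { x <- -x; vx <- -vx }
          if (x > arena_cm) { x <- 2 * arena_cm - x; vx <- -vx }
          if (y < 0) { y <- -y; vy <- -vy }
          if (y > arena_cm) { y <- 2 * arena_cm - y; vy <- -vy }
          xs[i] <- x; ys[i] <- y
        }
        dwall <- pmin(xs, arena_cm - xs, ys, arena_cm - ys)
        rate <- if (field == "border")
          base_rate + (peak_rate - base_rate) * exp(-dwall / d0_cm)
        else {
          dc <- sqrt((xs - arena_cm / 2)^2 + (ys - arena_cm / 2)^2)
          base_rate + (peak_rate - base_rate) * exp(-dc / (2 * d0_cm))
        }
        spikes <- stats::runif(n) < rate * dt
        list(xs = xs, ys = ys, spikes = spikes, rate = rate)
      })
      tt <- (seq_len(n) - 0.5) / frame_rate
      list(track = data.frame(t_s = tt, x_cm = sim$xs, y_cm = sim$ys),
           spike_times_s = tt[sim$spikes],
           frame_rate = frame_rate,
           truth = list(field = field, arena_cm = arena_cm,
                        peak_rate_hz = peak_rate, d0_cm = d0_cm,
                        rate_hz = sim$rate))
    })
}

#' Render a tuned population as a pixel movie
#'
#' Assigns each unit of a `"grating_tuned"` population to a square block of
#' pixels and adds independent pixel noise, producing a movie suitable for
#' pixelwise tuning analysis with exact per-pixel ground truth.
#'
#' @param pop result of `simulate_population("grating_tuned", ...)`.
#' @param nrow,ncol movie dimensions; `nrow * ncol` must be divisible into
#'   equal blocks across units.
#' @param pixel_noise_sd independent Gaussian noise per pixel sample.
#' @param seed integer seed.
#' @return a list with `movie` (a `vs_movie`), `pref_map` (per-pixel
#'   preferred direction) and the population `schedule`.
#' @export
population_movie <- function(pop, nrow = 32, ncol = 32,
                             pixel_noise_sd = 0.1, seed = 1) {
  n_units <- ncol(pop$traces)
  n_px <- nrow * ncol
  block <- sqrt(n_px / n_units)
  stopifnot(block == round(block))
  # unit u occupies a block x block tile, row-major tiling
  tiles_per_row <- ncol / block
  unit_of_px <- matrix(0L, nrow, ncol)
  for (r in seq_len(nrow)) for (cc in seq_len(ncol)) {
    tr <- ceiling(r / block); tc <- ceiling(cc / block)
    unit_of_px[r, cc] <- as.integer((tr - 1) * tiles_per_row + tc)
  }
  n_frames <- nrow(pop$traces)
  arr <- array(0, dim = c(n_frames, nrow, ncol))
  noise <- with_seed(seed, stats::rnorm(n_frames * n_px, 0, pixel_noise_sd))
  dim(noise) <- c(n_frames, nrow, ncol)
  for (r in seq_len(nrow)) for (cc in seq_len(ncol))
    arr[, r, cc] <- pop$traces[, unit_of_px[r, cc]] + noise[, r, cc]
  pref_map <- matrix(pop$truth$pref_deg[unit_of_px], nrow, ncol)
  list(movie = vs_movie(arr, pop$frame_rate), pref_map = pref_map,
       schedule = pop$schedule, unit_of_px = unit_of_px)
}
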