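# Shared fixtures, generated in code at test time.

# A kHz-rate photon-count recording with ground truth: spontaneous spiking
# on OU subthreshold, indicator forward model, Poisson photon emission.
# In-vivo-like conditions: ~1 Hz firing, 75-mV APs of 1 ms FWHM (cortical
# neurons at body temperature), the indicator's measured in-vivo effective
# repolarization (2.9 ms), and flux giving spike SNR (amplitude over shot
# noise) near 8.5.
invivo_model <- function(flux = 7.8e5)
  gevi_model(tau_off_ms = data.frame(tau_ms = 2.9, weight = 1),
             flux = flux)

photon_recording <- function(seed, duration_s = 60, rate_hz = 1,
                             flux = 7.8e5, amplitude_mV = 75,
                             frame_rate = 7100, sim_rate = 14200,
                             ou_sigma_mV = 2, ap_fwhm_ms = 1) {
  v <- simulate_voltage("spontaneous", duration_s = duration_s,
                        sim_rate = sim_rate, seed = seed,
                        rate_hz = rate_hz, ou_sigma_mV = ou_sigma_mV,
                        amplitude_mV = amplitude_mV, fwhm_ms = ap_fwhm_ms)
  model <- invivo_model(flux)
  dff <- voltage_to_dff(v, model)
  photons <- emit_photons(dff, model, frame_rate, seed = seed + 1000L)
  list(voltage = v, model = model, dff = dff, photons = photons,
       spike_snr = max(dff$values) * sqrt(mean(photons$values)))
}

# An imaging-rate (440 Hz) dF/F recording for the adaptive detector.
imaging_recording <- function(seed, duration_s = 30, rate_hz = 5,
                              flux = 2e6, frame_rate = 440) {
  v <- simulate_voltage("spontaneous", duration_s = duration_s,
                        sim_rate = 10000, seed = seed, rate_hz = rate_hz,
                        ou_sigma_mV = 1.5, amplitude_mV = 100)
  model <- gevi_model(flux = flux)
  ph <- emit_photons(voltage_to_dff(v, model), model, frame_rate,
                     seed = seed + 1000L)
  list(voltage = v,
       dff = vs_trace(ph$values / mean(ph$values) - 1, frame_rate, "dff"))
}

# Step-response kinetics fixture emulating the acquisition convention:
# noise drawn at the 80-kHz recording rate (per-sample SNR = amplitude /
# noise SD), then block-averaged 4x down to the 20-kHz analysis rate.
kinetics_step_fixture <- function(seed, taus_ms = c(2.4, 9.1),
                                  weights = c(0.5, 0.5), snr = 20,
                                  acq_rate = 80000, out_rate = 20000,
                                  t0 = 0.1, duration_s = 1.2) {
  n <- round(duration_s * acq_rate)
  tt <- (seq_len(n) - 0.5) / acq_rate
  y <- rep(sum(weights), n)
  post <- tt > t0
  y[post] <- 0
  for (i in seq_along(taus_ms))
    y[post] <- y[post] + weights[i] * exp(-(tt[post] - t0) /
                                            (taus_ms[i] / 1000))
  amp <- sum(weights)
  set.seed(seed)
  y <- y + stats::rnorm(n, 0, amp / snr)
  dec <- acq_rate / out_rate
  y20 <- colMeans(matrix(y, nrow = dec))
  vs_trace(y20, out_rate)
}

# Band-limited noise trace (0.1-2 Hz content) for cross-correlation tests.
slow_noise_trace <- function(seed, duration_s = 120, rate = 50) {
  set.seed(seed)
  n <- round(duration_s * rate)
  x <- stats::rnorm(n)
  voltscope:::fir_bandpass(x, rate, 0.1, 2)
}
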