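test_that("adaptive KDE threshold separates bimodal peaks and matches a
           brute-force oracle", {
  set.seed(1)
  peaks <- c(rnorm(500), rnorm(60, 8))
  th <- adaptive_kde_threshold(peaks)
  expect_gt(th$threshold, 2)
  expect_lt(th$threshold, 8)
  # oracle: direct Gaussian-mixture tail integrals on the same grid
  bw <- stats::bw.nrd(peaks); med <- stats::median(peaks)
  g_oracle <- vapply(th$grid, function(x0) {
    fm <- mean(stats::pnorm((x0 - peaks) / bw, lower.tail = FALSE))
    fn <- mean(stats::pnorm((x0 - (2 * med - peaks)) / bw,
                            lower.tail = FALSE))
    fm^0.1 - fn^0.1
  }, numeric(1))
  expect_equal(which.max(th$g), which.max(g_oracle))
  # pure symmetric noise: g stays near zero everywhere
  th0 <- adaptive_kde_threshold(rnorm(2000))
  expect_lt(max(abs(th0$g)), 0.15)
  expect_error(adaptive_kde_threshold(rnorm(5)), "insufficient")
})

test_that("adaptive detector finds generator spikes at imaging rates", {
  rec <- imaging_recording(seed = 5)
  det <- detect_adaptive_kde(rec$dff)
  pr <- precision_recall(match_spikes(rec$voltage$spike_times_s, det, 440))
  expect_gte(pr$precision, 0.95)
  expect_gte(pr$recall, 0.95)
  # event count is monotone non-increasing in the threshold scale
  n_at <- vapply(c(0.5, 1, 1.5, 2), function(s)
    length(detect_adaptive_kde(rec$dff, list(scale = s))), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("the delayed-differential detector resolves single spikes,
           bursts and stays silent on noise", {
  # flat trace plus one generator spike: exactly one event, onset close
  v <- simulate_voltage("spike_train", n_spikes = 1, duration_s = 4,
                        sim_rate = 14200, amplitude_mV = 75)
  m <- gevi_model(flux = 2e6)
  ph <- emit_photons(voltage_to_dff(v, m), m, 7100, seed = 2)
  det <- detect_ulove(ph)
  expect_equal(length(det), 1)
  expect_lt(abs(det$onset_times_s[1] - v$spike_times_s[1]), 5e-4)
  # pure Poisson noise, 60 s: no events at 20 sigma
  flat <- vs_trace(rep(0, 60 * 14200), 14200, "dff")
  phn <- emit_photons(flat, gevi_model(flux = 4e5), 7100, seed = 3)
  expect_equal(length(detect_ulove(phn)), 0)
  # 100 Hz burst of 4 spikes in a bright cell: all resolved as distinct
  # events (10-ms spacing exceeds the detector dead time)
  vb <- simulate_voltage("spike_train", n_spikes = 4, spike_rate_hz = 100,
                         duration_s = 2, sim_rate = 14200,
                         amplitude_mV = 75, fwhm_ms = 1)
  mb_model <- gevi_model(tau_off_ms = data.frame(tau_ms = 2.9,
                                                 weight = 1), flux = 5e6)
  phb <- emit_photons(voltage_to_dff(vb, mb_model), mb_model, 7100,
                      seed = 4)
  detb <- detect_ulove(phb)
  mb <- match_spikes(vb$spike_times_s, detb, 7100, window_frames = 25,
                     burst_isi_ms = NULL)
  expect_equal(mb$TP, 4)
  expect_error(detect_ulove(vs_trace(rnorm(1000), 100)), "config")
})

test_that("sliding-std detection calibrates false positives by trace
           inversion", {
  # symmetric noise: inverted and upright counts are statistically equal
  set.seed(6)
  nz <- vs_trace(rnorm(60 * 440), 440, "dff")
  r0 <- detect_sliding_std(nz)
  expect_gt(r0$fp_rate_estimate, 0.5)
  expect_lt(r0$fp_rate_estimate, 2)
  # generator data: upright count near truth, inversion near noise level
  rec <- imaging_recording(seed = 7)
  r1 <- detect_sliding_std(rec$dff)
  pr <- precision_recall(match_spikes(rec$voltage$spike_times_s,
                                      r1$spikes, 440))
  expect_gte(pr$recall, 0.9)
  # causal detrending rings after spikes, so the inverted trace
  # retains some events; the estimate must still be far below 1
  expect_lt(r1$fp_rate_estimate, 0.5)
  # raising k never increases the event count
  n_at <- vapply(c(3, 3.5, 4.5, 6), function(k)
    length(detect_sliding_std(rec$dff, list(k_sigma = k))$spikes),
    numeric(1))
  expect_true(all(diff(n_at) <= 0))
  expect_error(detect_sliding_std(vs_trace(rnorm(100), 5),
                                  list(window_s = 0.1)), "config")
})

test_that("singlet isolation equals the brute-force pairwise check", {
  tr <- vs_spikes(c(100L, 150L, 5000L, 20000L), 1000)
  expect_equal(length(isolate_singlets(tr, 100)), 2)   # doublet removed
  one <- vs_spikes(500L, 1000)
  expect_equal(length(isolate_singlets(one, 100)), 1)
  set.seed(8)
  idx <- sort(sample(1e5, 200))
  train <- vs_spikes(idx, 1000)
  for (gap in c(50, 100)) {
    got <- isolate_singlets(train, gap)$index
    ts <- idx / 1000
    keep <- vapply(seq_along(ts), function(i)
      all(abs(ts[-i] - ts[i]) >= gap / 1000 - 1e-12), logical(1))
    expect_identical(got, idx[keep])
  }
})

test_that("spike-triggered averages reproduce injected waveforms and
           scale SEM as 1/sqrt(n)", {
  rate <- 440
  y <- rep(0, 44000)
  spk_i <- seq(500, 43000, by = 350)
  wave <- c(1, 3, 6, 3, 1)
  for (i in spk_i) y[(i - 2):(i + 2)] <- wave
  tr <- vs_trace(y, rate)
  sta <- spike_triggered_average(tr, (spk_i - 0.5) / rate,
                                 window_s = c(0.1, 0.1),
                                 baseline_rule = "pre500ms")
  ctr <- round(0.1 * rate) + 1
  got <- sta$sta$values[(ctr - 2):(ctr + 2)]
  # identical snippets: zero SEM, exact waveform (above the common
  # baseline each snippet subtracts)
  expect_lt(max(sta$sem), 1e-12)
  expect_equal(got - min(sta$sta$values), wave, tolerance = 1e-9)
  # SEM scales as 1/sqrt(n) within 20%
  set.seed(10)
  yn <- y + rnorm(length(y), 0, 0.5)
  trn <- vs_trace(yn, rate)
  s_half <- spike_triggered_average(trn, (spk_i[1:40] - 0.5) / rate,
                                    window_s = c(0.1, 0.1),
                                    baseline_rule = "pre500ms")
  s_full <- spike_triggered_average(trn, (spk_i[1:120] - 0.5) / rate,
                                    window_s = c(0.1, 0.1),
                                    baseline_rule = "pre500ms")
  ratio <- mean(s_half$sem) / mean(s_full$sem)
  expect_equal(ratio, sqrt(3), tolerance = 0.2 * sqrt(3))
  # events too close to the edges are dropped and audited
  s_edge <- spike_triggered_average(tr, c(0.01, spk_i[5] / rate),
                                    window_s = c(0.1, 0.1))
  expect_equal(s_edge$n_dropped, 1)
  expect_error(spike_triggered_average(tr, 0.01,
                                       window_s = c(0.1, 0.1)), "empty")
})

test_that("SNR variants implement their noise conventions", {
  rate <- 440
  set.seed(11)
  y <- rnorm(44000, 0, 2)
  spk <- seq(1000, 43000, by = 400)
  y[spk] <- y[spk] + 50
  s1 <- spike_snr(vs_trace(y, rate), vs_spikes(spk, rate),
                  "resonant_baseline")
  expect_equal(s1$mean, 50 / 2, tolerance = 0.15)
  # shot noise: amplitude/sqrt(mean count), Poisson oracle
  ph <- rpois(44000, 100)
  ph[spk] <- ph[spk] + 100
  tr_ph <- vs_trace(ph, rate, units = "photons")
  s2 <- spike_snr(tr_ph, vs_spikes(spk, rate), "shot_noise")
  expect_equal(s2$mean, 100 / sqrt(100), tolerance = 0.1)
  expect_error(spike_snr(vs_trace(y, rate), vs_spikes(spk, rate),
                         "shot_noise"), "unit")
  # dynamic spike-free noise on pure noise: closed form for the SD of
  # half-rectified Gaussian deviations, 2 * sigma * sqrt(1/2 - 1/(2*pi))
  nz <- vs_trace(rnorm(30 * rate, 0, 1), rate)
  s3 <- spike_snr(nz, vs_spikes(c(2000L, 5000L), rate),
                  "dynamic_spikefree")
  det <- voltscope:::butter_filter(
    voltscope:::butter_filter(nz$values, rate, 0.25, "high",
                              zero_phase = FALSE),
    rate, 20, "high", zero_phase = FALSE)
  expected <- 2 * stats::sd(det) * sqrt(1 / 2 - 1 / (2 * pi))
  expect_equal(stats::median(s3$noise_trace, na.rm = TRUE), expected,
               tolerance = 0.15)
})

test_that("d-prime follows the photon-budget scaling laws", {
  set.seed(12)
  tr <- vs_trace(rpois(10000, 50), 7100, units = "photons")
  d1 <- dprime(tr, amplitude_dff = 1, window_ms = 2.6)
  tr2 <- tr; tr2$values <- tr$values * 2
  expect_equal(dprime(tr2, 1, 2.6) / d1, sqrt(2), tolerance = 1e-9)
  expect_equal(dprime(tr, 2, 2.6) / d1, 2)
  expect_error(dprime(vs_trace(rnorm(100), 100), 1, 2.6), "unit")
})

test_that("rolling spike rate equals a brute-force windowed count", {
  set.seed(13)
  times <- sort(runif(600, 0, 300))
  rr <- rolling_spike_rate(times, 300)
  # homogeneous Poisson: normalized rate near 1 throughout
  expect_lt(abs(mean(rr$rate_norm) - 1), 0.3)
  # brute-force oracle at every step
  first <- sum(times <= 60) / 60
  oracle <- vapply(rr$t_s, function(c0)
    sum(times >= c0 - 30 & times < c0 + 30) / 60 / first, numeric(1))
  expect_equal(rr$rate_norm, oracle)
  # empty second half drives the rate to zero
  rr2 <- rolling_spike_rate(times[times < 100], 300)
  expect_equal(rr2$rate_norm[rr2$t_s > 200], rep(0, sum(rr2$t_s > 200)))
})

test_that("subthreshold fluctuation is high state minus low state", {
  rate <- 1000
  # constant filtered trace: magnitude 0
  ct <- vs_trace(rep(3, 10000), rate)
  r0 <- subthreshold_fluctuation(ct, vs_spikes(5000L, rate))
  expect_equal(r0$magnitude, 0, tolerance = 1e-9)
  # all samples above the speed cutoff: masked-empty error
  sp <- vs_trace(rep(10, 10000), rate)
  expect_error(subthreshold_fluctuation(ct, vs_spikes(5000L, rate),
                                        speed = sp), "masked-empty")
  # generator up state of known optical gain recovered within 15%;
  # sampling the high state on the plateau between spikes isolates the
  # subthreshold component from spike-transient leakage through the
  # 50-Hz low-pass edge of the band
  v <- simulate_voltage("burst_on_up_state", duration_s = 40,
                        sim_rate = 10000, seed = 3, n_spikes = 0,
                        up_mV = 24, up_duration_s = 3)
  m <- gevi_model()
  d <- voltage_to_dff(v, m)
  tr <- vs_trace(d$values, 10000, "dff")
  up <- v$up_state_intervals[[1]]
  onsets <- seq(up[1] + 0.5, up[2] - 0.5, by = 0.25)
  idx <- as.integer(round(onsets * 10000))
  res <- subthreshold_fluctuation(tr, vs_spikes(idx, 10000))
  injected <- model_sigmoid(m, -70 + 24) - model_sigmoid(m, -70)
  expect_equal(res$magnitude, injected, tolerance = 0.15)
})
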