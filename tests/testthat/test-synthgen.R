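test_that("steps protocol holds -70 mV between the listed 1-s step levels", {
  v <- simulate_voltage("steps", sim_rate = 2000)
  expect_s3_class(v, "vs_voltage")
  levels <- c(90, 70, 50, 30, 20, 0, -20, -40, -60, -80, -100, -120)
  expect_equal(v$steps$level_mV, levels)
  # hold value before the first step and between steps
  expect_true(all(v$v_mV[v$time_s < 4] == -70))
  for (i in seq_len(nrow(v$steps))) {
    on <- v$steps$onset_s[i]
    expect_true(all(v$v_mV[v$time_s > on + 0.01 & v$time_s < on + 0.99] ==
                      levels[i]))
    expect_true(all(v$v_mV[v$time_s > on + 1.01 & v$time_s < on + 1.99] ==
                      -70))
  }
})

test_that("spike_train with zero spikes is a flat hold with empty truth", {
  v <- simulate_voltage("spike_train", n_spikes = 0, duration_s = 2,
                        sim_rate = 5000)
  expect_identical(v$spike_times_s, numeric(0))
  expect_true(all(v$v_mV == -70))
})

test_that("AP waveforms carry the configured amplitude and FWHM", {
  v <- simulate_voltage("spike_train", n_spikes = 1, duration_s = 2,
                        sim_rate = 50000, fwhm_ms = 2, amplitude_mV = 100)
  expect_equal(max(v$v_mV) - (-70), 100, tolerance = 1e-6)
  above <- which(v$v_mV > -70 + 50)
  fwhm <- (max(above) - min(above) + 1) / 50000 * 1000
  expect_equal(fwhm, 2, tolerance = 0.05)
})

test_that("spontaneous spike counts match a brute-force thinning oracle", {
  counts <- vapply(1:8, function(s)
    length(simulate_voltage("spontaneous", duration_s = 60,
                            sim_rate = 2000, seed = s,
                            rate_hz = 5)$spike_times_s), numeric(1))
  # oracle: gaps are refractory + Exp(rate); expected count follows the
  # renewal rate duration / (refractory + 1/rate)
  expected <- 60 / (0.005 + 1 / 5)
  expect_true(all(abs(counts - expected) < 3 * sqrt(expected)))
  # refractory gap respected
  v <- simulate_voltage("spontaneous", duration_s = 60, sim_rate = 2000,
                        seed = 1, rate_hz = 20, refractory_s = 0.01)
  expect_true(all(diff(v$spike_times_s) >= 0.01))
})

test_that("unknown protocol and low sim rate raise configuration errors", {
  expect_error(simulate_voltage("nope"), "protocol")
  expect_error(simulate_voltage("steps", sim_rate = 500), "sim_rate")
})

test_that("kinetic relaxation matches the analytic RC solution for one
           component", {
  m <- gevi_model(tau_on_ms = data.frame(tau_ms = 5, weight = 1),
                  tau_off_ms = data.frame(tau_ms = 5, weight = 1))
  v <- simulate_voltage("spike_train", n_spikes = 0, duration_s = 0.4,
                        sim_rate = 10000)
  v$v_mV[1001:2000] <- 30          # step up then back
  d <- voltage_to_dff(v, m)
  s30 <- model_sigmoid(m, 30); s70 <- model_sigmoid(m, -70)
  t_rel <- (1:1000) / 10000
  charge <- s30 + (s70 - s30) * exp(-t_rel / 0.005)
  expect_lt(max(abs(d$values[1001:2000] - charge)), 1e-6)
  f_at_return <- d$values[2000]
  discharge <- s70 + (f_at_return - s70) * exp(-t_rel / 0.005)
  expect_lt(max(abs(d$values[2001:3000] - discharge)), 1e-6)
})

test_that("held voltage converges to the sigmoid steady state", {
  m <- gevi_model()
  v <- simulate_voltage("spike_train", n_spikes = 0, duration_s = 0.5,
                        sim_rate = 10000)
  v$v_mV[] <- 30
  d <- voltage_to_dff(v, m)
  expect_lt(abs(d$values[length(d$values)] - model_sigmoid(m, 30)), 1e-3)
  # monotone approach for a monotone step
  expect_true(all(diff(d$values) >= -1e-12))
})

test_that("baseline anchoring gives dF/F = 0 at rest", {
  m <- gevi_model()
  expect_lt(abs(model_sigmoid(m, -70)), 1e-9)
  v <- simulate_voltage("spike_train", n_spikes = 0, duration_s = 0.2,
                        sim_rate = 5000)
  expect_lt(max(abs(voltage_to_dff(v, m)$values)), 1e-9)
})

test_that("photon emission is Poisson with the configured mean", {
  dd <- vs_trace(rep(0, 200000), 10000, "dff")
  m <- gevi_model(flux = 1e5)
  ph <- emit_photons(dd, m, 1000, seed = 2)
  expect_equal(mean(ph$values), 100, tolerance = 0.01)
  disp <- stats::var(ph$values) / mean(ph$values)
  expect_gt(disp, 0.95); expect_lt(disp, 1.05)
  # dark: zero flux gives all-zero counts
  expect_true(all(emit_photons(dd, gevi_model(flux = 0), 1000,
                               seed = 1)$values == 0))
})

test_that("the bleach envelope decays as the analytic exponential", {
  m <- gevi_model(flux = 1e6,
                  bleach = data.frame(amplitude = 1, tau_s = 10))
  dd <- vs_trace(rep(0, 30 * 2000), 2000, "dff")
  ph <- emit_photons(dd, m, 100, seed = 3)
  t <- trace_time(ph)
  expected <- 1e6 / 100 * exp(-t / 10)
  expect_lt(max(abs(ph$values - expected) / sqrt(expected)), 5)
  # 1 + dff < 0 is a model error
  bad <- vs_trace(rep(-1.5, 1000), 1000, "dff")
  expect_error(emit_photons(bad, m, 100), "negative")
})

test_that("generators are bitwise reproducible for a fixed seed", {
  a <- simulate_voltage("spontaneous", duration_s = 5, sim_rate = 2000,
                        seed = 42, ou_sigma_mV = 2)
  b <- simulate_voltage("spontaneous", duration_s = 5, sim_rate = 2000,
                        seed = 42, ou_sigma_mV = 2)
  expect_identical(a$v_mV, b$v_mV)
  expect_identical(a$spike_times_s, b$spike_times_s)
  m <- gevi_model(flux = 1e4)
  p1 <- emit_photons(voltage_to_dff(a, m), m, 200, seed = 9)
  p2 <- emit_photons(voltage_to_dff(b, m), m, 200, seed = 9)
  expect_identical(p1$values, p2$values)
})

test_that("rendered movies record their ground truth exactly", {
  nf <- 20
  cells <- list(list(center = c(10, 10), radius = 3, flux = 100,
                     dff = rep(0, nf)))
  # static, noiseless: every frame identical
  sc <- scene_spec(24, 24, 30, cells, nf, poisson = FALSE)
  rm_ <- render_movie(sc)
  expect_true(all(apply(rm_$movie$data, 1, function(f)
    identical(f, rm_$movie$data[1, , ] * 1))))
  # shift bookkeeping is the injection, exactly
  mot <- cbind(c(0, 1, -2, rep(0, nf - 3)), c(0, -1, 3, rep(0, nf - 3)))
  sc2 <- scene_spec(24, 24, 30, cells, nf, motion = mot, seed = 4)
  expect_identical(render_movie(sc2)$truth$shifts, mot)
  # a cell overlapping the edge after maximal shift errors
  cells_edge <- list(list(center = c(3, 3), radius = 3, flux = 10,
                          dff = rep(0, nf)))
  expect_error(scene_spec(24, 24, 30, cells_edge, nf, motion = mot),
               "scene error")
})

test_that("anticorrelated cells yield anticorrelated mask traces", {
  nf <- 200
  s <- sin(2 * pi * (1:nf) / 50)
  cells <- list(
    list(center = c(10, 10), radius = 3, flux = 500, dff = 0.5 * s),
    list(center = c(25, 25), radius = 3, flux = 500, dff = -0.5 * s))
  rm_ <- render_movie(scene_spec(36, 36, 30, cells, nf, seed = 6))
  t1 <- mask_trace(rm_$movie, rm_$masks[[1]])
  t2 <- mask_trace(rm_$movie, rm_$masks[[2]])
  expect_lt(stats::cor(t1$values, t2$values), 0)
})

test_that("population generators record ground truth for recovery", {
  # delta tuning: infinite kappa responds only at the preferred direction
  pop <- simulate_population("grating_tuned",
                             params = list(n_units = 1, kappa = Inf,
                                           prefs = 90, n_trials = 4,
                                           noise_sd = 0, frame_rate = 50,
                                           period_deg = 360),
                             seed = 1)
  tc <- tuning_curve(vs_trace(pop$traces[, 1], 50), pop$schedule)
  expect_gt(tc$mean_dff[tc$direction_deg == 90], 0.3)
  expect_true(all(abs(tc$mean_dff[tc$direction_deg != 90]) < 0.05))
  # zero injected lag: noiseless cross-correlation peaks at lag 0
  pop2 <- simulate_population("ach_coupled",
                              params = list(duration_s = 60,
                                            frame_rate = 50,
                                            lag_rad = 0, noise_sd = 0),
                              seed = 2)
  env <- voltscope:::fir_bandpass(
    voltscope:::hilbert_amplitude(
      voltscope:::fir_bandpass(pop2$voltage$values, 50, 2, 10)),
    50, 0.1, 1)
  mod <- voltscope:::fir_bandpass(pop2$modulator$values, 50, 0.1, 1)
  cl <- crosscorr_lag(vs_trace(env, 50), vs_trace(mod, 50),
                      band_hz = NULL, max_lag_s = 1.5)
  expect_lt(abs(cl$peak_lag_s), 0.1)
  # border unit: spikes concentrate near the walls
  pop3 <- simulate_population("arena_border",
                              params = list(duration_s = 300,
                                            d0_cm = 2,
                                            peak_rate_hz = 20,
                                            base_rate_hz = 0),
                              seed = 3)
  tr <- pop3$track
  idx <- findInterval(pop3$spike_times_s, tr$t_s)
  dwall <- pmin(tr$x_cm[idx], 80 - tr$x_cm[idx], tr$y_cm[idx],
                80 - tr$y_cm[idx])
  expect_gt(mean(dwall < 5), 0.8)
})
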