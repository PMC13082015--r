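test_that("background mode matches a brute-force histogram argmax", {
  # uniform frame
  mv <- vs_movie(array(7, c(2, 10, 10)), 30)
  expect_equal(estimate_background(mv), 7)
  # mode of the majority: mostly zeros plus a bright cell
  fr <- matrix(0, 20, 20); fr[5:8, 5:8] <- 50
  mv2 <- vs_movie(array(rep(fr, 2), c(20, 20, 2)), 30)
  mv2$data <- aperm(array(fr, c(20, 20, 2)), c(3, 1, 2))
  expect_equal(estimate_background(mv2), 0)
  # bimodal integer histogram vs exhaustive tabulation
  set.seed(1)
  px <- c(rpois(300, 10), rpois(100, 60))
  fr3 <- matrix(px, 20, 20)
  mv3 <- vs_movie(aperm(array(fr3, c(20, 20, 1)), c(3, 1, 2)), 30)
  tab <- table(px)
  expect_equal(estimate_background(mv3),
               as.numeric(names(tab)[which.max(tab)]))
  # all-saturated first frame errors
  mv4 <- vs_movie(array(10, c(1, 4, 4)), 30, saturation = 10)
  expect_error(estimate_background(mv4), "saturated")
})

make_scene_movie <- function(motion = NULL, n_frames = 40, seed = 2) {
  cells <- list(
    list(center = c(16, 16), radius = 5, flux = 200,
         dff = rep(0, n_frames)),
    list(center = c(34, 40), radius = 4, flux = 150,
         dff = rep(0, n_frames)))
  render_movie(scene_spec(48, 56, 30, cells, n_frames,
                          neuropil_gain = 20, motion = motion,
                          poisson = TRUE, seed = seed))
}

test_that("motion correction recovers injected shifts", {
  # zero injected motion: all shifts zero
  rm0 <- make_scene_movie()
  mc0 <- motion_correct(rm0$movie)
  expect_true(all(mc0$shifts == 0))
  # integer shifts recovered exactly by the integer stage
  set.seed(9)
  n <- 40
  mot <- cbind(sample(-3:3, n, TRUE), sample(-3:3, n, TRUE))
  mot <- sweep(mot, 2, round(apply(mot, 2, stats::median)))
  rm1 <- make_scene_movie(motion = mot)
  mc1 <- motion_correct(rm1$movie)
  got <- as.matrix(mc1$shifts)
  # absolute reference is unobservable; compare relative to frame 1
  expect_identical(unname(sweep(got, 2, got[1, ])),
                   sweep(mot, 2, mot[1, ]) * 1)
  expect_false(mc1$excluded)
  # subpixel jitter recovered within 0.5 px RMS by the local stage
  rm2 <- make_scene_movie(n_frames = 60, seed = 5)
  sub <- cbind(runif(60, -1, 1), runif(60, -1, 1)); sub[1, ] <- 0
  d <- rm2$movie$data
  for (f in 2:60)
    d[f, , ] <- voltscope:::bilinear_shift(d[f, , ], sub[f, 2], sub[f, 1])
  mc2 <- motion_correct(vs_movie(d, 30), local_window_s = 1)
  rms <- sqrt(mean((as.matrix(mc2$shifts) - sub)^2))
  expect_lt(rms, 0.5)
  # a large-motion recording is flagged for exclusion at 10 um mean shift
  mot_big <- cbind(rep(c(-6L, 6L), 20), 0L)
  rm3 <- make_scene_movie(motion = NULL, n_frames = 40)
  d3 <- rm3$movie$data
  for (f in 1:40)
    d3[f, , ] <- voltscope:::shift_matrix(d3[f, , ], 0, mot_big[f, 1],
                                          fill = 20)
  mc3 <- motion_correct(vs_movie(d3, 30), pixel_size_um = 2)
  expect_true(mc3$excluded)
  # constant frames are degenerate: zero shifts plus a warning flag
  mc4 <- motion_correct(vs_movie(array(5, c(4, 8, 8)), 30))
  expect_true(mc4$degenerate)
  expect_true(all(mc4$shifts == 0))
})

test_that("pixel selection maximizes prefix SNR over the correlation
           ranking", {
  nf <- 200
  side <- 24
  sig <- c(rep(0, 80), rep(3, 40), rep(0, 80))
  set.seed(3)
  arr <- array(rnorm(nf * side^2, 0, 0.5), c(nf, side, side))
  mask <- matrix(FALSE, side, side); mask[5:20, 5:20] <- TRUE
  signal_px <- matrix(FALSE, side, side); signal_px[5:12, 5:20] <- TRUE
  for (r in 5:12) for (cc in 5:20) arr[, r, cc] <- arr[, r, cc] + sig
  mv <- vs_movie(arr, 100)
  ps <- select_pixels(mv, mask, min_pixels = 300)
  # the chosen prefix picks signal-carrying pixels
  expect_gt(sum(ps$selected & signal_px) / sum(ps$selected), 0.95)
  # equals the exhaustive search over prefixes of the stored ranking
  expect_equal(ps$chosen, which.max(ps$snr_curve))
  expect_true(all(diff(ps$r) <= 1e-12))      # ranking is by decreasing r
  # a 256-pixel mask is rejected under the 300-pixel minimum
  expect_true(ps$rejected)
  expect_false(select_pixels(mv, mask, min_pixels = 100)$rejected)
  # identical pixels: all correlations 1, full mask retained as optimum
  arr2 <- array(rep(sig + 1, side^2), c(nf, side, side))
  ps2 <- select_pixels(vs_movie(arr2, 100), mask, min_pixels = 10)
  expect_true(all(abs(ps2$r - 1) < 1e-12))
})

test_that("bleach model selection picks the generating order", {
  t <- (1:3000 - 0.5) / 10
  # noiseless single exponential: order 1, tau within 1%
  f1 <- fit_bleach(vs_trace(0.8 * exp(-t / 20) + 0.2, 10))
  expect_equal(f1$model_order, 1)
  expect_equal(f1$taus_s, 20, tolerance = 0.01)
  # noiseless double exponential: order 2 wins, order 3 rejected
  f2 <- fit_bleach(vs_trace(0.5 * exp(-t / 5) + 0.3 * exp(-t / 60) + 0.2,
                            10))
  expect_equal(f2$model_order, 2)
  expect_equal(sort(f2$taus_s), c(5, 60), tolerance = 0.02)
  # constant trace: identity correction
  fc <- fit_bleach(vs_trace(rep(2, 500), 10))
  expect_true(all(abs(fc$amplitudes) < 1e-9))
  tr <- vs_trace(rep(2, 500), 10)
  expect_lt(max(abs(bleach_correct(tr, fc)$values - 2)), 1e-9)
  # correction flattens a generator bleach curve
  tr2 <- vs_trace(0.8 * exp(-t / 20) + 0.2, 10)
  corr <- bleach_correct(tr2, f1)
  trend <- stats::coef(stats::lm(corr$values ~ t))[2] * 60
  expect_lt(abs(trend), 1e-3)     # residual slope under 1e-3 per minute
  # excluded intervals are honored
  y3 <- 0.8 * exp(-t / 20) + 0.2
  y3[t > 100 & t < 120] <- 5
  f3 <- fit_bleach(vs_trace(y3, 10),
                   exclude_intervals = list(c(99, 121)))
  expect_equal(f3$taus_s[which.max(abs(f3$amplitudes))], 20,
               tolerance = 0.02)
})

test_that("dF/F baselines implement their conventions", {
  # constant traces map to exactly zero under every method
  ct <- vs_trace(rep(5, 3000), 100)
  for (m in c("rolling_p5", "mean", "lowpass_divide"))
    expect_true(all(compute_dff(ct, m)$values == 0))
  expect_true(all(compute_dff(ct, "blank_window",
                              list(blank_onsets_s = c(0, 10)))$values == 0))
  # step from 100 to 150 with a pre-step mean baseline: plateau 0.5
  y <- c(rep(100, 100), rep(150, 100))
  d <- compute_dff(vs_trace(y, 100), "mean",
                   list(window_s = c(0, 0.99)))
  expect_equal(d$values[150], 0.5, tolerance = 1e-12)
  # rolling 5th percentile tracks the spike-free baseline within 2%
  set.seed(4)
  n <- 60 * 100
  base <- 100 * exp(-(1:n) / (100 * 2000))
  yy <- base + rnorm(n, 0, 0.5)
  spikes <- sample(n - 10, 120)
  for (s in spikes) yy[s:(s + 3)] <- yy[s:(s + 3)] + 60
  d2 <- compute_dff(vs_trace(yy, 100), "rolling_p5",
                    list(window_s = 30))
  f0_implied <- yy / (1 + d2$values)
  mid <- 1000:(n - 1000)
  expect_lt(stats::median(abs(f0_implied[mid] - base[mid]) / base[mid]),
            0.02)
  # non-positive baseline errors
  expect_error(compute_dff(vs_trace(c(rep(-1, 50), rep(-1.2, 50)), 10),
                           "mean"), "baseline")
})

test_that("power-law bleach slope matches the closed form", {
  t <- (1:100000 - 0.5) / 500
  expect_equal(bleach_power_law(vs_trace(t^(-0.3), 500), t_start_s = 60),
               -0.3, tolerance = 1e-3)
  expect_equal(bleach_power_law(vs_trace(rep(2, 50000), 500),
                                t_start_s = 60), 0)
  # early bi-exponential phase excluded: tail slope matches a tail-only fit
  y <- 0.5 * exp(-t / 5) + t^(-0.25)
  got <- bleach_power_law(vs_trace(y, 500), t_start_s = 60)
  tail_fit <- stats::coef(stats::lm(log10(y[t >= 60]) ~
                                      log10(t[t >= 60])))[2]
  expect_equal(got, unname(tail_fit), tolerance = abs(tail_fit) * 0.05)
})

test_that("quadratic power correction rescales by (P_ref/P)^2", {
  v <- c(1, 0.5, 0.25)
  expect_equal(power_correct(v, c(10, 10, 10), normalize = FALSE), v)
  # doubled power at one wavelength divides that value by 4
  expect_equal(power_correct(c(1, 1), c(10, 20), normalize = FALSE),
               c(1, 0.25))
  # known power jitter on a flat spectrum recovers flat truth
  set.seed(5)
  p <- runif(20, 8, 12)
  meas <- 3 * (p / 10)^2
  corr <- power_correct(meas, p, p_ref = 10, normalize = TRUE)
  expect_lt(max(abs(corr - 1)), 1e-12)
  expect_error(power_correct(1, 0), "power")
})
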