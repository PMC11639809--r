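test_that("the band-pass filter matches the analytic Butterworth response", {
  fps <- 20
  n <- 600
  tt <- (0:(n - 1)) / fps
  # a constant (DC) input is rejected (away from the edge transient)
  out0 <- bandpass(rep(5, n), fps)
  mid0 <- 150:450
  expect_lt(max(abs(out0[mid0])), 0.05)
  # in-band tone passes essentially unattenuated; forward-backward filtering
  # applies the squared analytic magnitude response
  x5 <- sin(2 * pi * 0.5 * tt)
  y5 <- bandpass(x5, fps)
  mid <- 150:450
  gain5 <- sqrt(mean(y5[mid]^2)) / sqrt(mean(x5[mid]^2))
  expect_gt(gain5, 0.9)
  expect_lt(gain5, 1.02)
  expect_equal(gain5, butter_bp_gain(0.5, fps)^2, tolerance = 0.02)
  # out-of-band tone is crushed
  x2 <- sin(2 * pi * 2 * tt)
  y2 <- bandpass(x2, fps)
  gain2 <- sqrt(mean(y2[mid]^2)) / sqrt(mean(x2[mid]^2))
  expect_lt(gain2, 0.01)
  expect_lt(gain2, 3 * butter_bp_gain(2, fps)^2 + 1e-6)
  # band edge above Nyquist must error
  expect_error(bandpass(x5, fps = 1.2), class = "ovirr_parameter_error")
  expect_error(bandpass(c(1, 2), fps), class = "ovirr_parameter_error")
})

test_that("PCA recovers a planted common component and conserves variance", {
  set.seed(8)
  n <- 400; fps <- 20
  s <- sin(2 * pi * 0.5 * (0:(n - 1)) / fps)
  mix <- outer(runif(12, 0.5, 2), s) + matrix(rnorm(12 * n, 0, 0.05), 12)
  mo <- structure(list(dx = mix[1:6, ], dy = mix[7:12, ], fps = fps),
                  class = "motion_signals")
  comps <- pca_decompose(mo)
  expect_gt(abs(cor(comps$scores[, 1], s)), 0.99)
  # total variance is conserved across the rotation
  total_var <- sum(apply(mix, 1, stats::var))
  expect_equal(sum(comps$explained_var), total_var, tolerance = 1e-9)
  expect_gt(comps$explained_var[1] / total_var, 0.9)
  # a stronger sinusoid must come out as component 1, the weaker as 2
  s2 <- 0.2 * sin(2 * pi * 0.4 * (0:(n - 1)) / fps + 1)
  mix2 <- rbind(outer(rep(1, 6), s), outer(rep(1, 6), s2))
  mo2 <- structure(list(dx = mix2[1:6, ], dy = mix2[7:12, ], fps = fps),
                   class = "motion_signals")
  comps2 <- pca_decompose(mo2)
  expect_gt(abs(cor(comps2$scores[, 1], s)), 0.99)
  expect_gt(abs(cor(comps2$scores[, 2], s2)), 0.99)
})

test_that("component selection honours the configured strategy", {
  set.seed(9)
  n <- 400; fps <- 20
  tt <- (0:(n - 1)) / fps
  inband <- sin(2 * pi * 0.5 * tt)
  out1 <- 3 * sin(2 * pi * 3 * tt)
  out2 <- 2 * sin(2 * pi * 2.2 * tt)
  rows <- rbind(outer(rep(1, 4), out1) + matrix(rnorm(4 * n, 0, 0.01), 4),
                outer(rep(1, 4), out2) + matrix(rnorm(4 * n, 0, 0.01), 4),
                outer(rep(1, 4), inband) + matrix(rnorm(4 * n, 0, 0.01), 4))
  mo <- structure(list(dx = rows[1:6, ], dy = rows[7:12, ], fps = fps),
                  class = "motion_signals")
  comps <- pca_decompose(mo)
  first <- select_component(comps, fps, strategy = "first")
  expect_equal(first$component_index, 1L)
  best <- select_component(comps, fps, strategy = "best_inband")
  expect_gt(best$component_index, 1L)
  expect_gt(abs(cor(best$samples, inband)), 0.99)
  expect_lt(abs(mean(best$samples)), 1e-9)  # zero-meaned
  expect_error(select_component(comps, fps, strategy = "nope"))
})

test_that("sliding-window RR estimation matches the brute-force oracle", {
  fps <- 10
  n <- 120
  set.seed(14)
  for (i in 1:10) {
    f <- runif(1, 0.36, 0.64)
    x <- sin(2 * pi * f * (0:(n - 1)) / fps + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, 0.2)
    sig <- structure(list(samples = x, fps = fps, component_index = 1L),
                     class = "respiratory_signal")
    got <- estimate_rr(sig, window_s = 10, pad_len = 256L)
    want <- estimate_rr_oracle(x, fps, window_s = 10, pad_len = 256)
    expect_equal(got$rr_bpm, want, tolerance = 1e-9)
  }
})

test_that("estimate_rr recovers a pure tone to within one frequency bin", {
  fps <- 20
  n <- 600
  x <- sin(2 * pi * 0.45 * (0:(n - 1)) / fps)
  sig <- structure(list(samples = x, fps = fps, component_index = 1L),
                   class = "respiratory_signal")
  series <- estimate_rr(sig)
  wf <- round(10 * fps)
  expect_length(series$rr_bpm, n - wf + 1)
  bin_bpm <- 60 * fps / 4096
  # spectral leakage of the 4.5-cycle window allows at most ~2 bins of drift
  expect_true(all(abs(series$rr_bpm - 27) <= 2 * bin_bpm + 1e-9))
  expect_equal(median(series$rr_bpm), 27, tolerance = 0.02)
  expect_equal(series$times_s[1], wf / fps, tolerance = 1e-9)
  expect_equal(diff(series$times_s), rep(1 / fps, length(series$times_s) - 1),
               tolerance = 1e-9)

  # an out-of-band distractor, even a stronger one, cannot win the argmax
  x2 <- sin(2 * pi * 0.4 * (0:(n - 1)) / fps) +
    5 * sin(2 * pi * 1.5 * (0:(n - 1)) / fps)
  sig2 <- structure(list(samples = x2, fps = fps, component_index = 1L),
                    class = "respiratory_signal")
  series2 <- estimate_rr(sig2)
  expect_lt(abs(median(series2$rr_bpm) - 24), 0.5)
  expect_true(all(abs(series2$rr_bpm - 24) <= 2))

  # signals shorter than one window are rejected
  short <- structure(list(samples = x[1:50], fps = fps, component_index = 1L),
                     class = "respiratory_signal")
  expect_error(estimate_rr(short), class = "ovirr_degenerate_input")
})

test_that("RR smoothing preserves constants and the series mean exactly", {
  s_const <- rr_series(times_s = (1:50) / 10, rr_bpm = rep(27, 50), fps = 10)
  sm <- smooth_rr(s_const, kernel_s = 1)
  expect_equal(sm$rr_smoothed_bpm, rep(27, 50), tolerance = 1e-12)

  # a sinusoid whose period equals the (11-tap) kernel averages to its DC
  # level at every interior sample
  per <- rr_series(times_s = (1:60) / 10,
                   rr_bpm = 27 + sin(2 * pi * (0:59) / 11), fps = 10)
  sm2 <- smooth_rr(per, kernel_s = 1.1)
  expect_true(all(abs(sm2$rr_smoothed_bpm[6:55] - 27) < 1e-9))
  # mirror-pad smoothing conserves the mean to numerical precision
  expect_equal(mean(sm2$rr_smoothed_bpm), mean(per$rr_bpm), tolerance = 1e-9)

  set.seed(5)
  noisy <- rr_series(times_s = (1:200) / 20, rr_bpm = 27 + rnorm(200, 0, 2),
                     fps = 20)
  sm3 <- smooth_rr(noisy, kernel_s = 3)
  expect_equal(mean(sm3$rr_smoothed_bpm), mean(noisy$rr_bpm), tolerance = 1e-9)
  expect_lt(sd(sm3$rr_smoothed_bpm), sd(noisy$rr_bpm))

  expect_error(smooth_rr(rr_series(numeric(0), numeric(0)), kernel_s = 1),
               class = "ovirr_degenerate_input")
})
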