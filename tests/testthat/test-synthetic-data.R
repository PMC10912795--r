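test_that("background generator hits its rms target and is deterministic", {
  x <- gen_background(10, 1000, alpha = 1, rms = 50, seed = 42)
  expect_equal(sqrt(mean(x^2)), 50, tolerance = 1e-10)
  expect_identical(x, gen_background(10, 1000, alpha = 1, rms = 50, seed = 42))
  expect_false(identical(x, gen_background(10, 1000, 1, 50, seed = 43)))
  expect_error(gen_background(10, 1000, alpha = NaN, rms = 50),
               class = "lfpdbs_validation_error")
})

test_that("alpha = 0 background is white: flat Welch PSD from 1 Hz to fs/4", {
  fs <- 1000
  dens <- rowMeans(sapply(1:5, function(s) {
    x <- gen_background(30, fs, alpha = 0, rms = 10, seed = s)
    welch_psd(x, welch_config(window_s = 1), fs = fs)$density[, 1]
  }))
  freqs <- welch_psd(gen_background(1, fs, 0, 1, 1),
                     welch_config(window_s = 1), fs = fs)$freqs
  sel <- freqs >= 1 & freqs <= fs / 4
  expect_lt(max(dens[sel]) / min(dens[sel]), 2)  # within 3 dB
})

test_that("alpha = 1 background has log-log PSD slope near -1 over 1-100 Hz", {
  fs <- 1000
  slopes <- sapply(1:20, function(s) {
    x <- gen_background(20, fs, alpha = 1, rms = 50, seed = s)
    p <- welch_psd(x, welch_config(window_s = 2), fs = fs)
    sel <- p$freqs >= 1 & p$freqs <= 100
    unname(coef(lm(log(p$density[sel, 1]) ~ log(p$freqs[sel])))[2])
  })
  expect_gt(mean(slopes), -1.2)
  expect_lt(mean(slopes), -0.8)
})

test_that("PAC generator: no coupling at depth 0, more coupling at higher depth", {
  fs <- 1000
  theta <- band_def("theta", 4, 12)
  gamma <- band_def("gamma", 60, 100)
  mi0 <- band_mi(gen_pac_signal(8, 80, 0, 1, 30, fs, 1),
                 gen_pac_signal(8, 80, 0, 1, 30, fs, 1), fs, theta, gamma)
  expect_lte(mi0, 0.01)

  mono <- sapply(1:10, function(s) {
    mis <- sapply(c(0, 0.3, 0.9), function(chi) {
      x <- gen_pac_signal(8, 80, chi, 1, 20, fs, s)
      band_mi(x, x, fs, theta, gamma)
    })
    mis[3] > mis[2] && mis[2] > mis[1]
  })
  expect_true(all(mono))
})

test_that("PAC envelope at full depth tracks the phase-frequency sinusoid", {
  fs <- 1000
  x <- gen_pac_signal(8, 80, 1, 1, 30, fs, 1, noise_rms = 0)
  env <- extract_amplitude(x, fs, band_def("g", 60, 100))
  tt <- (1000:(30 * fs - 1000 - 1)) / fs
  expect_gt(cor(env, sin(2 * pi * 8 * tt)), 0.9)
})

test_that("PAC generator validates its frequency layout", {
  expect_error(gen_pac_signal(8, 600, 0.5, fs = 1000),
               class = "lfpdbs_nyquist_error")
  expect_error(gen_pac_signal(80, 8, 0.5, fs = 1000),
               class = "lfpdbs_validation_error")
})

test_that("coherent pair hits the closed-form limits", {
  fs <- 500
  theta <- band_def("theta", 4, 12)
  p1 <- gen_coherent_pair(1, theta, 20, 30, fs, 1)
  expect_gt(band_coherence(msc(p1[, 1], p1[, 2], fs), theta), 0.98)
  p0 <- gen_coherent_pair(0, theta, 20, 30, fs, 1)
  expect_lt(band_coherence(msc(p0[, 1], p0[, 2], fs), theta), 0.1)
})

test_that("assembled recordings are deterministic with exact ground truth", {
  sz <- data.frame(onset_s = 20, duration_s = 10)
  sp <- synth_spec(60, fs = 500, seed = 8, seizures = sz,
                   oscillations = list(list(band = band_def("theta", 4, 12),
                                            rms = 20)))
  out1 <- assemble_recording(sp)
  out2 <- assemble_recording(sp)
  expect_identical(out1$recording$samples, out2$recording$samples)
  expect_equal(out1$events$onset_s, 20)
  expect_equal(out1$events$termination_s, 30)
  expect_equal(out1$events$score, 4L)
})

test_that("a seizure-free assembled recording is stationary", {
  sp <- synth_spec(20, fs = 500, seed = 3,
                   background = list(alpha = 0.5, rms = 50))
  out <- assemble_recording(sp)
  expect_equal(nrow(out$events), 0L)
  v <- sapply(0:9, function(k)
    var(slice_recording(out$recording, 2 * k, 2 * (k + 1))$samples[, 1]))
  expect_lt(max(abs(v - mean(v)) / mean(v)), 0.2)
})

test_that("ictal broadband power gain matches the configured factor", {
  sz <- data.frame(onset_s = 30, duration_s = 20, broadband_gain = 10,
                   spikewave_hz = 3, spike_rms = 1e-3)
  sp <- synth_spec(60, fs = 500, seed = 12, seizures = sz,
                   background = list(alpha = 1, rms = 50))
  rec <- assemble_recording(sp)$recording
  p_pre <- mean(slice_recording(rec, 5, 29)$samples[, 1]^2)
  p_ict <- mean(slice_recording(rec, 31, 49)$samples[, 1]^2)
  expect_gt(p_ict / p_pre, 5)
  expect_lt(p_ict / p_pre, 15)
})

test_that("component powers add within tolerance", {
  fs <- 500
  tot <- sapply(1:10, function(s) {
    sp <- synth_spec(20, fs = fs, seed = s,
                     background = list(alpha = 1, rms = 30),
                     oscillations = list(list(band = band_def("theta", 4, 12),
                                              rms = 20)),
                     pair_coupling = list(lambda = 0.5,
                                          band = band_def("gamma", 30, 80),
                                          rms = 15))
    mean(assemble_recording(sp)$recording$samples[, 1]^2)
  })
  expected <- 30^2 + 20^2 + 15^2
  expect_lt(abs(mean(tot) - expected) / expected, 0.1)
})

test_that("invalid seizure schedules are rejected", {
  expect_error(synth_spec(60, seizures = data.frame(
    onset_s = c(10, 15), duration_s = c(10, 5))),
    class = "lfpdbs_validation_error")
  expect_error(synth_spec(60, seizures = data.frame(
    onset_s = 55, duration_s = 10)),
    class = "lfpdbs_validation_error")
  expect_error(synth_spec(60, seizures = data.frame(
    onset_s = 10, duration_s = 5, broadband_gain = 0.5)),
    class = "lfpdbs_validation_error")
})
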