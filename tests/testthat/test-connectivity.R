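test_that("coherence is 1 for identical signals and bounded in [0,1]", {
  set.seed(1)
  x <- rnorm(10000)
  cs <- msc(x, x, fs = 500)
  expect_true(all(abs(cs$msc - 1) < 1e-10))

  y <- rnorm(10000)
  cs2 <- msc(x, y, fs = 500)
  expect_true(all(cs2$msc >= 0 & cs2$msc <= 1))
  # symmetry in channel order
  cs3 <- msc(y, x, fs = 500)
  expect_equal(cs2$msc, cs3$msc, tolerance = 1e-12)
})

test_that("independent noises have low band coherence", {
  fs <- 500
  vals <- sapply(1:5, function(s) {
    set.seed(s)
    x <- rnorm(30 * fs); y <- rnorm(30 * fs)
    band_coherence(msc(x, y, fs), band_def("theta", 4, 12))
  })
  expect_lt(mean(vals), 0.1)
})

test_that("single-window coherence is rejected", {
  expect_error(msc(rnorm(1000), rnorm(1000), fs = 500,
                   wcfg = welch_config(window_s = 2, overlap_frac = 0)),
               class = "lfpdbs_validation_error")
})

test_that("shared-source pairs reach the closed-form lambda^4 coherence", {
  fs <- 500
  theta <- band_def("theta", 4, 12)
  vals <- sapply(1:8, function(s) {
    p <- gen_coherent_pair(0.8, theta, 20, 30, fs, s)
    band_coherence(msc(p[, 1], p[, 2], fs), theta)
  })
  expect_lt(abs(mean(vals) - 0.8^4), 0.08)
})

test_that("extracted phase advances linearly and bins uniformly", {
  fs <- 900; f <- 10                       # 90 samples/cycle = 5 per bin
  n <- 20 * fs
  x <- sin(2 * pi * f * (0:(n - 1)) / fs)
  ph <- extract_phase(x, fs, band_def("b", 8, 12), edge_trim_s = 1)
  un <- cumsum(c(ph[1], Arg(exp(1i * diff(ph)))))
  tt <- (fs:(n - fs - 1)) / fs
  slope <- unname(coef(lm(un ~ tt))[2])
  expect_lt(abs(slope - 2 * pi * f) / (2 * pi * f), 0.001)

  cnt <- tabulate(floor((ph + pi) / (2 * pi / 18)) + 1, 18)
  expect_lt(max(abs(cnt - mean(cnt)) / mean(cnt)), 0.02)
})

test_that("phase matches an independent quadrature-pair oracle", {
  fs <- 1000
  set.seed(2)
  x <- gen_background(20, fs, 1, 50, seed = 7)
  band <- band_def("theta", 4, 12)
  ph <- extract_phase(x, fs, band, edge_trim_s = 0)
  xf <- lfpdbs:::bandpass_fft(x, fs, band$f_lo, band$f_hi)
  expect_lt(max(abs(Arg(exp(1i * (ph - oracle_quadrature_phase(xf)))))),
            1e-6)
})

test_that("envelope extraction behaves at the amplitude extremes", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  # constant-amplitude carrier: flat envelope
  am <- extract_amplitude(sin(2 * pi * 80 * t), fs, band_def("g", 60, 100))
  expect_lt(sd(am) / mean(am), 0.05)
  # fully modulated carrier: envelope reaches ~0
  x1 <- gen_pac_signal(8, 80, 1, 1, 20, fs, 1, noise_rms = 0)
  env <- extract_amplitude(x1, fs, band_def("g", 60, 100))
  expect_lt(min(env) / max(env), 0.05)
  # zero signal: zero envelope
  z <- extract_amplitude(numeric(5000), fs, band_def("g", 60, 100))
  expect_true(all(z < 1e-12))
})

test_that("modulation index matches closed forms and the brute-force oracle", {
  set.seed(3)
  ph <- runif(20000, -pi, pi)
  expect_equal(modulation_index(ph, rep(2.5, 20000)), 0)   # flat profile

  # all amplitude concentrated in one bin
  amp1 <- as.numeric(ph >= -pi + 4 * 2 * pi / 18 & ph < -pi + 5 * 2 * pi / 18)
  expect_equal(modulation_index(ph, amp1), 1)

  for (i in 1:10) {
    phi <- runif(3000, -pi, pi)
    a <- rexp(3000)
    expect_equal(modulation_index(phi, a), oracle_mi(phi, a),
                 tolerance = 1e-12)
  }

  # scale invariance
  phi <- runif(3000, -pi, pi); a <- rexp(3000)
  expect_equal(modulation_index(phi, a), modulation_index(phi, 137.2 * a),
               tolerance = 1e-12)

  expect_error(modulation_index(runif(10, -pi, 0), rexp(10)),
               class = "lfpdbs_insufficient_data_error")
  expect_error(modulation_index(runif(10, -pi, pi), rexp(9)),
               class = "lfpdbs_validation_error")
})

test_that("modulation index increases with generator depth", {
  fs <- 1000
  theta <- band_def("theta", 4, 12)
  gamma <- band_def("gamma", 60, 100)
  chis <- c(0, 0.25, 0.5, 0.75, 1)
  mi_mean <- rowMeans(sapply(1:3, function(s)
    sapply(chis, function(chi) {
      x <- gen_pac_signal(8, 80, chi, 1, 20, fs, s)
      band_mi(x, x, fs, theta, gamma)
    })))
  expect_equal(cor(mi_mean, chis, method = "spearman"), 1)
})

test_that("comodulogram uses the documented grid and recovers the coupling", {
  fs <- 1000
  cfg <- mi_config()
  expect_equal(length(cfg$phase_freqs), 23L)   # 1-12 Hz in 0.5 Hz steps
  expect_equal(length(cfg$amp_freqs), 44L)     # 35-250 Hz in 5 Hz steps
  expect_equal(cfg$n_bins, 18L)

  x <- gen_pac_signal(8, 80, 0.9, 1, 25, fs, 5)
  cm <- comodulogram(x, x, fs)
  expect_equal(dim(cm$mi), c(23L, 44L))
  k <- arrayInd(which.max(cm$mi), dim(cm$mi))
  expect_lte(abs(cm$phase_freqs[k[1]] - 8), 1)
  expect_lte(abs(cm$amp_freqs[k[2]] - 80), 10)
  expect_true(all(cm$mi >= 0 & cm$mi <= 1))

  x0 <- gen_pac_signal(8, 80, 0, 1, 25, fs, 5)
  cm0 <- comodulogram(x0, x0, fs)
  expect_lt(max(cm0$mi), 0.01)
})

test_that("comodulogram validates grid and segment length", {
  expect_error(comodulogram(rnorm(3000), rnorm(3000), fs = 400,
                            cfg = mi_config(decimate_to = 400)),
               class = "lfpdbs_validation_error")  # 250 Hz grid > Nyquist
  expect_error(comodulogram(rnorm(2000), rnorm(2000), fs = 1000),
               class = "lfpdbs_validation_error")  # < 10 slow cycles
})
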