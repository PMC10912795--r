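test_that("peri-ictal segmentation applies the 30/5/30 s window arithmetic", {
  rec <- make_noise_recording(duration_s = 200, fs = 200, seed = 1,
                              channels = "HC")
  ev <- seizure_events(100, 140, 4)
  segs <- segment_around_seizure(rec, ev[1, ], segmentation_config())
  expect_equal(segs$pre$t0, 70)
  expect_equal(nrow(segs$pre$samples), 30 * 200L)
  expect_equal(segs$ictal$t0, 100)
  expect_equal(nrow(segs$ictal$samples), 5 * 200L)
  expect_equal(segs$post$t0, 140)
  expect_equal(nrow(segs$post$samples), 30 * 200L)
  # pre never overlaps ictal: boundary sample belongs to ictal
  expect_equal(segs$ictal$samples[1, 1], rec$samples[100 * 200 + 1, 1])
  expect_equal(segs$pre$samples[30 * 200, 1], rec$samples[100 * 200, 1])
  # concatenating pre + ictal equals the contiguous slice
  expect_equal(rbind(segs$pre$samples, segs$ictal$samples),
               slice_recording(rec, 70, 105)$samples)
})

test_that("segmentation refuses windows beyond the recording", {
  rec <- make_noise_recording(duration_s = 60, fs = 100, seed = 2,
                              channels = "HC")
  expect_error(segment_around_seizure(rec, list(onset_s = 10,
                                                termination_s = 20)),
               class = "lfpdbs_boundary_error")
  expect_error(segment_around_seizure(rec, list(onset_s = 35,
                                                termination_s = 50)),
               class = "lfpdbs_boundary_error")
})

test_that("Welch PSD recovers sinusoid power and satisfies Parseval", {
  fs <- 1000
  t <- (0:(30 * fs - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 10 * t), welch_config(), fs = fs)
  expect_equal(band_power(psd, band_def("theta", 8, 12)), 0.5,
               tolerance = 0.04)

  set.seed(3)
  w <- rnorm(30 * fs)
  psd_w <- welch_psd(w, welch_config(), fs = fs)
  expect_equal(band_power(psd_w, band_def("all", 0, fs / 2)), var(w),
               tolerance = 0.05)

  z <- welch_psd(numeric(5000), welch_config(), fs = fs)
  expect_true(all(z$density == 0))
  expect_error(welch_psd(rnorm(100), welch_config(window_s = 1), fs = 1000),
               class = "lfpdbs_validation_error")
})

test_that("PSD scales quadratically with amplitude", {
  set.seed(4)
  x <- rnorm(10000)
  p1 <- welch_psd(x, welch_config(), fs = 500)
  p3 <- welch_psd(3 * x, welch_config(), fs = 500)
  expect_equal(p3$density, 9 * p1$density, tolerance = 1e-12)
})

test_that("band power integrates the density exactly and additively", {
  freqs <- seq(0, 100, by = 0.5)
  flat <- structure(list(freqs = freqs,
                         density = matrix(2, length(freqs), 1),
                         fs = 200),
                    class = "psd_result")
  expect_equal(band_power(flat, band_def("b", 20, 30)), 20)  # 10 Hz x 2

  set.seed(5)
  rough <- structure(list(freqs = freqs,
                          density = matrix(rexp(length(freqs)),
                                           length(freqs), 1),
                          fs = 200),
                     class = "psd_result")
  cuts <- c(0.5, 4, 12, 30, 55, 95, 100)
  parts <- sapply(seq_len(length(cuts) - 1), function(i)
    band_power(rough, band_def("p", cuts[i], cuts[i + 1])))
  expect_equal(sum(parts), band_power(rough, band_def("all", 0.5, 100)),
               tolerance = 1e-12)
  expect_error(band_power(flat, band_def("x", 150, 200)),
               class = "lfpdbs_validation_error")
})

test_that("an 8 Hz sinusoid concentrates power in theta", {
  fs <- 1000
  t <- (0:(30 * fs - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 8 * t), welch_config(), fs = fs)
  bands <- default_bands()
  th <- band_power(psd, bands$theta)
  expect_gt(th / (band_power(psd, bands$delta) + 1e-30), 100)
  expect_gt(th / (band_power(psd, bands$gamma) + 1e-30), 100)
})

test_that("post/pre ratios pair records correctly", {
  tab <- data.frame(seizure_id = rep(1:2, each = 4),
                    period = rep(c("pre", "post"), 4),
                    channel = "HC",
                    band = rep(rep(c("delta", "theta"), each = 2), 2),
                    value = c(1, 1, 2, 4, 3, 6, 5, 5))
  r <- post_pre_ratio(tab)
  expect_equal(nrow(r), 4L)
  expect_equal(r$ratio[r$seizure_id == 1 & r$band == "delta"], 1)
  expect_equal(r$ratio[r$seizure_id == 1 & r$band == "theta"], 2)
  expect_equal(r$ratio[r$seizure_id == 2 & r$band == "delta"], 2)
  expect_equal(r$ratio[r$seizure_id == 2 & r$band == "theta"], 1)

  # brute-force dictionary pairing on a randomized table
  set.seed(6)
  ids <- 1:6; bands <- c("delta", "theta", "gamma")
  full <- expand.grid(seizure_id = ids, period = c("pre", "post"),
                      channel = c("HC", "mPFC"), band = bands,
                      stringsAsFactors = FALSE)
  full$value <- rexp(nrow(full)) + 0.1
  r2 <- post_pre_ratio(full)
  for (k in sample(nrow(r2), 10)) {
    row <- r2[k, ]
    pre <- full$value[full$seizure_id == row$seizure_id &
                      full$period == "pre" & full$channel == row$channel &
                      full$band == row$band]
    post <- full$value[full$seizure_id == row$seizure_id &
                       full$period == "post" & full$channel == row$channel &
                       full$band == row$band]
    expect_equal(row$ratio, post / pre)
  }

  expect_error(post_pre_ratio(tab[-1, ]), class = "lfpdbs_pairing_error")
  tab0 <- tab
  tab0$value[tab0$period == "pre" & tab0$seizure_id == 1 &
             tab0$band == "delta"] <- 0
  expect_warning(r0 <- post_pre_ratio(tab0), "zero pre-ictal")
  expect_equal(nrow(r0), 3L)
})
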