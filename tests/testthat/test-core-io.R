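test_that("EDF round-trip preserves fs, labels and samples to quantization", {
  rec <- make_noise_recording(duration_s = 1, fs = 1000, seed = 3)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)

  expect_equal(back$fs, rec$fs)
  expect_equal(back$channels, rec$channels)
  qstep <- apply(abs(rec$samples), 2L, max) / 32767
  for (j in 1:2)
    expect_lt(max(abs(back$samples[, j] - rec$samples[, j])), qstep[j])
})

test_that("EDF round-trip handles non-integer-second durations", {
  rec <- make_noise_recording(duration_s = 0.75, fs = 400, seed = 9)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, 400)
  expect_equal(nrow(back$samples), 300L)
})

test_that("malformed EDF headers are rejected", {
  path <- withr::local_tempfile(fileext = ".edf")
  # syntactically complete header announcing zero signals
  con <- file(path, "wb")
  hdr <- paste0(formatC("0", width = 8, flag = "-"),
                strrep(" ", 160),
                formatC("01.01.00", width = 8), formatC("00.00.00", width = 8),
                formatC("256", width = 8, flag = "-"),
                strrep(" ", 44),
                formatC("1", width = 8, flag = "-"),
                formatC("1", width = 8, flag = "-"),
                formatC("0", width = 4, flag = "-"))
  writeChar(hdr, con, eos = NULL)
  close(con)
  expect_error(read_edf(path), class = "lfpdbs_format_error")

  # truncated file
  path2 <- withr::local_tempfile(fileext = ".edf")
  writeBin(as.raw(1:100), path2)
  expect_error(read_edf(path2), class = "lfpdbs_format_error")
})

test_that("a generator-produced EDF fixture preserves channel variance", {
  x <- gen_background(2, 1000, alpha = 1, rms = 50, seed = 11)
  rec <- recording(cbind(HC = x), fs = 1000)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_lt(abs(var(back$samples[, 1]) - var(x)) / var(x), 0.05)
})

test_that("event CSVs round-trip and are validated", {
  ev <- seizure_events(c(10, 2), c(15, 5), c(4, 3))
  expect_equal(ev$onset_s, c(2, 10))  # sorted

  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  expect_equal(read_events(path), ev)

  # 100 random non-overlapping events round-trip identically
  set.seed(5)
  gaps <- runif(100, 1, 5)
  onsets <- cumsum(runif(100, 5, 20))
  ev2 <- seizure_events(onsets, onsets + gaps, sample(0:5, 100, TRUE))
  write_events(ev2, path)
  expect_equal(read_events(path), ev2)

  expect_error(seizure_events(10, 5, 4), class = "lfpdbs_validation_error")
  expect_error(seizure_events(10, 15, 2.5), class = "lfpdbs_validation_error")
  expect_error(seizure_events(c(0, 5), c(6, 9), c(4, 4)),
               class = "lfpdbs_validation_error")  # overlap
  writeLines("a,b\n1,2", path)
  expect_error(read_events(path), class = "lfpdbs_format_error")
})

test_that("stim log CSVs round-trip", {
  ep <- schedule_episode(10, stim_protocol(n_packages = 2,
                                           pulses_per_package = 5,
                                           inter_package_gap_s = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stim_log(ep$pulses, path)
  back <- read_stim_log(path)
  expect_equal(back$time_s, ep$pulses$time_s)
  expect_equal(back$package_idx, ep$pulses$package_idx)
})

test_that("slice obeys the half-open sample contract", {
  rec <- make_noise_recording(duration_s = 2, fs = 1000, seed = 2)
  expect_equal(nrow(slice_recording(rec, 0, 1)$samples), 1000L)
  # identity slice
  expect_equal(slice_recording(rec, 0, 2)$samples, rec$samples)
  # concatenation identity
  a <- slice_recording(rec, 0, 0.7)
  b <- slice_recording(rec, 0.7, 2)
  expect_equal(rbind(a$samples, b$samples), rec$samples)
  expect_error(slice_recording(rec, 1, 3), class = "lfpdbs_bounds_error")
  expect_error(slice_recording(rec, -0.1, 1), class = "lfpdbs_bounds_error")
})

test_that("slice lengths are exact over random boundaries", {
  rec <- make_noise_recording(duration_s = 3, fs = 250, seed = 4)
  set.seed(7)
  for (i in 1:25) {
    i0 <- sample(0:(750 - 2), 1)
    i1 <- sample((i0 + 1):750, 1)
    s <- slice_recording(rec, i0 / 250, i1 / 250)
    expect_identical(nrow(s$samples), i1 - i0)
    expect_equal(s$samples[, 1], rec$samples[(i0 + 1):i1, 1])
  }
})
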