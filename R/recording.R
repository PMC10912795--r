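#' Construct a multi-channel LFP recording
#'
#' A `lfp_recording` holds per-channel amplitude series in microvolts (uV),
#' a common sampling rate and a start time. All time arguments throughout the
#' package are seconds relative to the same clock as `t0`, samples are
#' 0-based, and every interval is half-open `[start, end)`.
#'
#' @param samples numeric matrix, one column per channel (uV), or a list of
#'   equal-length numeric vectors.
#' @param fs sampling rate in Hz (> 0). Default 10000 Hz, the acquisition
#'   rate the package assumes for in-vivo recordings.
#' @param channels character vector of channel labels, e.g. `c("HC","mPFC")`.
#' @param t0 recording start time in seconds.
#' @return object of class `lfp_recording` with fields `samples` (matrix),
#'   `fs`, `channels`, `t0`.
#' @examples
#' rec <- recording(cbind(sin(2 * pi * 8 * (0:999) / 1000)), fs = 1000,
#'                  channels = "HC")
#' rec_duration(rec)
#' @export
recording <- function(samples, fs = 10000, channels = NULL, t0 = 0) {
  if (is.list(samples) && !is.data.frame(samples)) {
    n <- unique(vapply(samples, length, integer(1)))
    if (length(n) != 1L)
      stop_lfpdbs("all channels must have equal length", "lfpdbs_validation_error")
    if (is.null(channels)) channels <- names(samples)
    samples <- do.call(cbind, samples)
  }
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L)
    stop_lfpdbs("recording must contain at least one sample", "lfpdbs_validation_error")
  check_scalar_num(fs, "fs", lo = 0, open_lo = TRUE)
  check_scalar_num(t0, "t0")
  if (is.null(channels)) channels <- colnames(samples)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  if (length(channels) != ncol(samples))
    stop_lfpdbs("length(channels) must match number of channels", "lfpdbs_validation_error")
  colnames(samples) <- channels
  structure(list(samples = samples, fs = fs, channels = channels, t0 = t0),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) [%s], fs = %g Hz, %d samples (%.3f s), t0 = %g s\n",
              ncol(x$samples), paste(x$channels, collapse = ", "),
              x$fs, nrow(x$samples), nrow(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
summary.lfp_recording <- function(object, ...) {
  s <- apply(object$samples, 2L, function(v) c(mean = mean(v), sd = sd(v),
                                               min = min(v), max = max(v)))
  print(object)
  print(round(t(s), 4))
  invisible(t(s))
}

#' Duration of a recording in seconds
#' @param rec an `lfp_recording`.
#' @return duration in seconds (`n_samples / fs`).
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Extract one channel as a numeric vector
#' @param rec an `lfp_recording`.
#' @param channel channel label.
#' @return numeric vector of samples (uV).
#' @export
rec_channel <- function(rec, channel) {
  if (!channel %in% rec$channels)
    stop_lfpdbs(sprintf("channel '%s' not present", channel), "lfpdbs_config_error")
  rec$samples[, channel]
}

#' Slice a recording to a half-open time interval
#'
#' Returns the samples in `[t_start, t_end)` (times on the recording clock,
#' i.e. compared against `t0`). The slice contract is exact:
#' `round((t_end - t_start) * fs)` samples are returned, channel order is
#' preserved, and out-of-range requests raise an error rather than silently
#' truncating.
#'
#' @param rec an `lfp_recording`.
#' @param t_start,t_end interval bounds in seconds, `t0 <= t_start < t_end`.
#' @return an `lfp_recording` with `t0 = t_start`.
#' @examples
#' rec <- recording(cbind(rnorm(1000)), fs = 1000)
#' nrow(slice_recording(rec, 0, 0.5)$samples)  # 500
#' @export
slice_recording <- function(rec, t_start, t_end) {
  check_scalar_num(t_start, "t_start")
  check_scalar_num(t_end, "t_end")
  n <- nrow(rec$samples)
  if (t_start < rec$t0 - 1e-9 || t_end > rec$t0 + n / rec$fs + 1e-9 ||
      t_start >= t_end)
    stop_lfpdbs(sprintf("slice [%g, %g) out of recording extent [%g, %g)",
                        t_start, t_end, rec$t0, rec$t0 + n / rec$fs),
                "lfpdbs_bounds_error")
  i0 <- round((t_start - rec$t0) * rec$fs)
  len <- round((t_end - t_start) * rec$fs)
  if (i0 + len > n)
    stop_lfpdbs("slice exceeds recording end", "lfpdbs_bounds_error")
  recording(rec$samples[(i0 + 1):(i0 + len), , drop = FALSE],
            fs = rec$fs, channels = rec$channels, t0 = t_start)
}

#' Frequency band definition
#'
#' The canonical peri-ictal bands are delta (< 4 Hz, floored at 0.5 Hz),
#' theta (4-12 Hz) and gamma (30-150 Hz); see [default_bands()].
#'
#' @param name band label.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi`.
#' @return a `band_def` list.
#' @export
band_def <- function(name, f_lo, f_hi) {
  check_scalar_num(f_lo, "f_lo", lo = 0)
  check_scalar_num(f_hi, "f_hi", lo = f_lo, open_lo = TRUE)
  structure(list(name = as.character(name), f_lo = f_lo, f_hi = f_hi),
            class = "band_def")
}

#' @export
print.band_def <- function(x, ...) {
  cat(sprintf("<band> %s: [%g, %g) Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Default analysis bands
#'
#' Delta is implemented as `[0.5, 4)` Hz (a 0.5 Hz high-pass floor below the
#' printed "< 4 Hz" definition, matching detrending practice), theta as
#' `[4, 12)`, gamma as `[30, 150)`. With `gamma_subbands = TRUE` the gamma
#' range is replaced by slow `[30, 55)`, middle `[55, 95)` and fast
#' `[95, 150)` sub-bands, chosen to keep 50/60 Hz mains away from boundaries.
#'
#' @param gamma_subbands logical; include gamma sub-bands instead of the
#'   single gamma band.
#' @return named list of [band_def()] objects.
#' @export
default_bands <- function(gamma_subbands = FALSE) {
  b <- list(delta = band_def("delta", 0.5, 4),
            theta = band_def("theta", 4, 12))
  if (gamma_subbands) {
    b$gamma_slow <- band_def("gamma_slow", 30, 55)
    b$gamma_mid  <- band_def("gamma_mid", 55, 95)
    b$gamma_fast <- band_def("gamma_fast", 95, 150)
  } else {
    b$gamma <- band_def("gamma", 30, 150)
  }
  b
}

#' Seizure event table constructor
#'
#' @param onset_s electrographic onset times (s).
#' @param termination_s end of ictal discharges (s); must exceed onset.
#' @param score integer 0-5 behavioral severity (modified Racine scale).
#' @return data.frame of class `seizure_events`, sorted by onset.
#' @export
seizure_events <- function(onset_s = numeric(), termination_s = numeric(),
                           score = integer()) {
  if (length(onset_s) != length(termination_s) ||
      length(onset_s) != length(score))
    stop_lfpdbs("onset_s, termination_s, score must have equal length",
                "lfpdbs_validation_error")
  score <- suppressWarnings(as.numeric(score))
  if (length(score) && (any(!is.finite(score)) || any(score != round(score)) ||
                        any(score < 0 | score > 5)))
    stop_lfpdbs("score must be an integer in 0..5", "lfpdbs_validation_error")
  if (length(onset_s) && any(termination_s <= onset_s))
    stop_lfpdbs("termination_s must exceed onset_s", "lfpdbs_validation_error")
  o <- order(onset_s)
  ev <- data.frame(onset_s = as.numeric(onset_s)[o],
                   termination_s = as.numeric(termination_s)[o],
                   score = as.integer(score)[o])
  if (nrow(ev) > 1L && any(ev$onset_s[-1L] < ev$termination_s[-nrow(ev)]))
    stop_lfpdbs("seizure events must not overlap", "lfpdbs_validation_error")
  class(ev) <- c("seizure_events", "data.frame")
  ev
}

#' Read seizure annotations from CSV
#'
#' Expects a header with columns `onset_s`, `termination_s`, `score`.
#' Events are validated (termination after onset, integer score 0-5,
#' no overlap) and returned sorted by onset.
#'
#' @param path CSV file path.
#' @return a `seizure_events` data.frame.
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "termination_s", "score")
  if (!all(need %in% names(d)))
    stop_lfpdbs(sprintf("events CSV must have columns %s",
                        paste(need, collapse = ", ")), "lfpdbs_format_error")
  seizure_events(d$onset_s, d$termination_s, d$score)
}

#' Write seizure annotations to CSV
#' @param events a `seizure_events` data.frame.
#' @param path output CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[c("onset_s", "termination_s", "score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulation pulse log from CSV
#'
#' Columns: `time_s`, `package_idx`, `width_s`, `amplitude`.
#' @param path CSV file path.
#' @return data.frame sorted by time with validated fields.
#' @export
read_stim_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "package_idx", "width_s", "amplitude")
  if (!all(need %in% names(d)))
    stop_lfpdbs("stim log CSV must have columns time_s, package_idx, width_s, amplitude",
                "lfpdbs_format_error")
  if (any(d$width_s <= 0))
    stop_lfpdbs("pulse width must be > 0", "lfpdbs_validation_error")
  d[order(d$time_s), need]
}

#' Write a stimulation pulse log to CSV
#' @param pulses data.frame with columns time_s, package_idx, width_s, amplitude.
#' @param path output CSV path.
#' @export
write_stim_log <- function(pulses, path) {
  utils::write.csv(pulses[c("time_s", "package_idx", "width_s", "amplitude")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
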