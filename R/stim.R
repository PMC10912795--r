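# Low-frequency stimulation scheduling, artifact injection and removal.
#
# The stimulation pattern is the pulse-package design used for hippocampal
# low-frequency DBS: a triggered episode delivers four packages of 200
# monophasic 0.1 ms square pulses at 1 Hz, packages separated by 5 minute
# intervals. Because monophasic stimulation with passive charge balancing
# leaves a brief discharge transient on the recording electrode, a matching
# artifact waveform (square pulse followed by an opposite-sign exponential
# decay of equal area) can be injected into synthetic data and removed by
# blank-and-interpolate before analysis.

#' Stimulation protocol parameters
#'
#' @param n_packages number of pulse packages per episode; default 4.
#' @param pulses_per_package pulses per package; default 200.
#' @param pulse_rate_hz within-package pulse rate; default 1 Hz.
#' @param pulse_width_s pulse width; default 1e-4 s (0.1 ms).
#' @param inter_package_gap_s the "5 min interval" between packages;
#'   default 300 s.
#' @param interval_mode how the 5 min interval is interpreted:
#'   `"gap-after-package-end"` (default; gap measured from the last pulse of
#'   one package to the first of the next) or `"start-to-start"` (package
#'   onsets are `inter_package_gap_s` apart; errors if a package is longer
#'   than the gap).
#' @return a `stim_protocol` list.
#' @export
stim_protocol <- function(n_packages = 4, pulses_per_package = 200,
                          pulse_rate_hz = 1, pulse_width_s = 1e-4,
                          inter_package_gap_s = 300,
                          interval_mode = c("gap-after-package-end",
                                            "start-to-start")) {
  check_scalar_num(n_packages, "n_packages", lo = 1)
  check_scalar_num(pulses_per_package, "pulses_per_package", lo = 1)
  check_scalar_num(pulse_rate_hz, "pulse_rate_hz", lo = 0, open_lo = TRUE)
  check_scalar_num(pulse_width_s, "pulse_width_s", lo = 0, open_lo = TRUE)
  check_scalar_num(inter_package_gap_s, "inter_package_gap_s", lo = 0)
  structure(list(n_packages = as.integer(n_packages),
                 pulses_per_package = as.integer(pulses_per_package),
                 pulse_rate_hz = pulse_rate_hz, pulse_width_s = pulse_width_s,
                 inter_package_gap_s = inter_package_gap_s,
                 interval_mode = match.arg(interval_mode)),
            class = "stim_protocol")
}

#' Schedule a stimulation episode at a trigger time
#'
#' Package `p` (0-based) contains `pulses_per_package` pulses spaced exactly
#' `1 / pulse_rate_hz` apart; the first pulse of the episode is at
#' `t_trigger`. With the default protocol each package spans 199 s
#' (first to last pulse) and the episode ends
#' `4 * 199 + 3 * 300 = 1696` s after the trigger.
#'
#' @param t_trigger trigger time (s), >= 0.
#' @param protocol a [stim_protocol()].
#' @param amplitude nominal pulse amplitude recorded in the log (arbitrary
#'   units; the in-tissue amplitude is not modeled).
#' @return object of class `stim_episode`: list with `t_trigger_s`,
#'   `t_end_s` (time of the last pulse) and `pulses`, a data.frame with
#'   columns `time_s`, `package_idx`, `width_s`, `amplitude`.
#' @export
schedule_episode <- function(t_trigger, protocol = stim_protocol(),
                             amplitude = 1) {
  check_scalar_num(t_trigger, "t_trigger", lo = 0)
  ipi <- 1 / protocol$pulse_rate_hz
  span <- (protocol$pulses_per_package - 1L) * ipi
  if (protocol$interval_mode == "start-to-start" &&
      span + protocol$pulse_width_s > protocol$inter_package_gap_s)
    stop_lfpdbs("package duration exceeds start-to-start interval",
                "lfpdbs_schedule_overlap_error")
  starts <- if (protocol$interval_mode == "gap-after-package-end")
    t_trigger + (span + protocol$inter_package_gap_s) *
      (seq_len(protocol$n_packages) - 1L)
  else
    t_trigger + protocol$inter_package_gap_s *
      (seq_len(protocol$n_packages) - 1L)
  pulses <- do.call(rbind, lapply(seq_along(starts), function(p)
    data.frame(time_s = starts[p] + ipi * (seq_len(protocol$pulses_per_package) - 1L),
               package_idx = p - 1L,
               width_s = protocol$pulse_width_s,
               amplitude = amplitude)))
  structure(list(t_trigger_s = t_trigger,
                 t_end_s = max(pulses$time_s) + protocol$pulse_width_s,
                 pulses = pulses),
            class = "stim_episode")
}

#' @export
print.stim_episode <- function(x, ...) {
  cat(sprintf("<stim_episode> trigger %.3f s, %d pulses in %d package(s), ends %.3f s\n",
              x$t_trigger_s, nrow(x$pulses),
              length(unique(x$pulses$package_idx)), x$t_end_s))
  invisible(x)
}

# Charge-balanced artifact waveform sampled at fs: square pulse of amplitude
# a0 and width w, then an opposite-sign exponential of time constant tau
# whose area matches the pulse area (passive discharge).
artifact_waveform <- function(fs, a0, width_s, tau_s) {
  npulse <- max(1L, round(width_s * fs))
  ndecay <- max(1L, round(8 * tau_s * fs))
  t <- (seq_len(ndecay) - 0.5) / fs
  decay <- exp(-t / tau_s)
  pulse_area <- a0 * npulse / fs
  decay <- -decay * pulse_area / (sum(decay) / fs)
  c(rep(a0, npulse), decay)
}

#' Inject stimulation artifacts into a recording
#'
#' Adds the charge-balanced artifact waveform at every pulse time of the
#' episode, on the stimulated channel only.
#'
#' @param rec an [recording()].
#' @param episode a [schedule_episode()] result, or a pulse data.frame with
#'   a `time_s` column.
#' @param artifact list `(a0, tau_s)`: pulse amplitude (uV) and discharge
#'   time constant (s); default 500 uV, 3 ms.
#' @param channel stimulated channel label; default the first channel.
#' @param pulse_width_s pulse width (s), used when `episode` is a bare
#'   pulse table without widths.
#' @return a new `lfp_recording` with artifacts added.
#' @export
inject_artifacts <- function(rec, episode,
                             artifact = list(a0 = 500, tau_s = 0.003),
                             channel = rec$channels[1L],
                             pulse_width_s = 1e-4) {
  pulses <- if (inherits(episode, "stim_episode")) episode$pulses else episode
  if (!nrow(pulses) || artifact$a0 == 0) return(rec)
  w <- if ("width_s" %in% names(pulses)) pulses$width_s[1L] else pulse_width_s
  wf <- artifact_waveform(rec$fs, artifact$a0, w, artifact$tau_s)
  x <- rec$samples
  j <- match(channel, rec$channels)
  n <- nrow(x)
  end_t <- rec$t0 + n / rec$fs
  if (any(pulses$time_s < rec$t0) || any(pulses$time_s >= end_t))
    stop_lfpdbs("pulse outside recording extent", "lfpdbs_bounds_error")
  for (tp in pulses$time_s) {
    i0 <- round((tp - rec$t0) * rec$fs)
    idx <- (i0 + 1):min(i0 + length(wf), n)
    x[idx, j] <- x[idx, j] + wf[seq_along(idx)]
  }
  recording(x, fs = rec$fs, channels = rec$channels, t0 = rec$t0)
}

#' Remove stimulation artifacts by blanking and interpolation
#'
#' Samples in `[time_s, time_s + blank_s)` around every pulse are replaced
#' by linear interpolation between the samples bounding the blanked window;
#' contiguous or overlapping windows are merged first. Interpolation is
#' exact for affine signals, and at 1 Hz stimulation the default 10 ms
#' blank discards 1% of the data. The operation is idempotent.
#'
#' @param rec an [recording()].
#' @param pulses pulse table with a `time_s` column (or a `stim_episode`).
#' @param blank_s blank window per pulse (s); default 0.01.
#' @param channel channel to clean; default the first channel.
#' @return a new `lfp_recording`.
#' @export
remove_artifacts <- function(rec, pulses, blank_s = 0.01,
                             channel = rec$channels[1L]) {
  if (inherits(pulses, "stim_episode")) pulses <- pulses$pulses
  if (is.null(pulses) || !nrow(pulses)) return(rec)
  tp <- sort(pulses$time_s)
  iv <- merge_intervals(cbind(tp, tp + blank_s))
  n <- nrow(rec$samples)
  j <- match(channel, rec$channels)
  x <- rec$samples[, j]
  for (r in seq_len(nrow(iv))) {
    i0 <- max(1L, round((iv[r, 1L] - rec$t0) * rec$fs) + 1L)
    i1 <- min(n, round((iv[r, 2L] - rec$t0) * rec$fs))
    if (i0 > i1) next
    if (i0 <= 1L && i1 >= n)
      stop_lfpdbs("blank window covers the whole recording",
                  "lfpdbs_validation_error")
    lo <- if (i0 > 1L) x[i0 - 1L] else x[i1 + 1L]
    hi <- if (i1 < n) x[i1 + 1L] else x[i0 - 1L]
    k <- i1 - i0 + 1L
    x[i0:i1] <- lo + (hi - lo) * seq_len(k) / (k + 1L)
  }
  out <- rec$samples
  out[, j] <- x
  recording(out, fs = rec$fs, channels = rec$channels, t0 = rec$t0)
}
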