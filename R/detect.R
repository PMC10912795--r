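# Online seizure-onset detection from windowed LFP power.
#
# The detector mirrors the classic responsive-stimulation design: short-term
# power is computed over consecutive 10 ms epochs, compared against a
# long-term (10 s) running baseline, and an onset is declared when 100
# consecutive epochs exceed a multiple of the baseline. It is strictly
# causal: the decision at an epoch uses only samples up to that epoch.

#' Detector configuration
#'
#' @param epoch_s epoch length (s); default 0.01 (10 ms).
#' @param n_consecutive number of consecutive supra-threshold epochs
#'   required; default 100 (so a sustained 1 s power rise triggers).
#' @param baseline_s trailing baseline window (s); default 10.
#' @param threshold_k power ratio over baseline required per epoch (> 1);
#'   default 4. Not a published constant — chosen as a wide margin over
#'   chi-square fluctuations of 10 ms noise power.
#' @param refractory_s dead time after each detection (s); default 60.
#' @param channel label of the monitored channel; default `"HC"`.
#' @return a `detector_config` list.
#' @export
detector_config <- function(epoch_s = 0.01, n_consecutive = 100,
                            baseline_s = 10, threshold_k = 4,
                            refractory_s = 60, channel = "HC") {
  check_scalar_num(epoch_s, "epoch_s", lo = 0, open_lo = TRUE)
  check_scalar_num(n_consecutive, "n_consecutive", lo = 1)
  check_scalar_num(baseline_s, "baseline_s", lo = epoch_s)
  check_scalar_num(threshold_k, "threshold_k", lo = 1, open_lo = TRUE)
  check_scalar_num(refractory_s, "refractory_s", lo = 0)
  structure(list(epoch_s = epoch_s, n_consecutive = as.integer(n_consecutive),
                 baseline_s = baseline_s, threshold_k = threshold_k,
                 refractory_s = refractory_s, channel = channel),
            class = "detector_config")
}

#' Short-term power per non-overlapping epoch
#'
#' Mean squared amplitude (uV^2) over consecutive non-overlapping epochs;
#' any trailing partial epoch is discarded.
#'
#' @param x numeric sample vector (uV).
#' @param fs sampling rate (Hz).
#' @param epoch_s epoch length (s).
#' @return numeric vector of length `floor(length(x) / round(epoch_s * fs))`.
#' @export
epoch_power <- function(x, fs, epoch_s = 0.01) {
  spl <- round(epoch_s * fs)
  if (spl < 1L || length(x) < spl)
    stop_lfpdbs("epoch longer than the series", "lfpdbs_validation_error")
  nep <- length(x) %/% spl
  colMeans(matrix(x[seq_len(nep * spl)]^2, nrow = spl))
}

#' Run the online power detector over a recording
#'
#' Single causal pass over non-overlapping epochs of the monitored channel.
#' The baseline is the mean epoch power over the trailing `baseline_s`
#' seconds of *clean* epochs — epochs inside `exclusions` (e.g. stimulation
#' periods), inside a candidate run, or inside a refractory period never
#' enter it, so ictal or artifactual data cannot inflate the baseline. A
#' detection is emitted when `n_consecutive` consecutive epochs each exceed
#' `threshold_k` times the baseline frozen at the start of the run;
#' `t_detect_s` is back-dated to the first epoch of the run so downstream
#' ictal windows cover the earliest ictal activity. After each detection the
#' detector is refractory for `refractory_s` seconds; during refractory the
#' baseline resumes tracking (so a sustained power shift is detected once,
#' not once per refractory period).
#'
#' @param rec an [recording()].
#' @param cfg a [detector_config()].
#' @param exclusions optional 2-column matrix (or data.frame) of half-open
#'   `[start, end)` intervals (s) to ignore, e.g. stimulation episodes.
#' @return data.frame of class `detections` with columns `t_detect_s`,
#'   `baseline_power` (uV^2, the frozen baseline at decision time).
#' @export
detect_onsets <- function(rec, cfg = detector_config(), exclusions = NULL) {
  x <- rec_channel(rec, cfg$channel)
  if (length(x) / rec$fs < cfg$baseline_s)
    stop_lfpdbs("recording shorter than the baseline window",
                "lfpdbs_validation_error")
  p <- epoch_power(x, rec$fs, cfg$epoch_s)
  nep <- length(p)
  tstart <- rec$t0 + (seq_len(nep) - 1L) * cfg$epoch_s

  excluded <- rep(FALSE, nep)
  if (!is.null(exclusions)) {
    exm <- as.matrix(exclusions)
    if (ncol(exm) >= 2L && nrow(exm)) for (r in seq_len(nrow(exm)))
      excluded <- excluded | (tstart < exm[r, 2L] &
                              tstart + cfg$epoch_s > exm[r, 1L])
  }

  n_base <- round(cfg$baseline_s / cfg$epoch_s)
  buf <- numeric(n_base); bn <- 0L; bi <- 0L; bsum <- 0
  run_len <- 0L; run_t0 <- NA_real_; run_base <- NA_real_
  refrac_until <- -Inf
  det_t <- numeric(); det_b <- numeric()

  push <- function(v) {
    bi <<- bi %% n_base + 1L
    if (bn == n_base) bsum <<- bsum - buf[bi] else bn <<- bn + 1L
    buf[bi] <<- v
    bsum <<- bsum + v
  }

  i <- 1L
  while (i <= nep) {
    ti <- tstart[i]
    if (excluded[i]) { i <- i + 1L; next }
    if (ti < refrac_until) {
      # refractory: no detection, but the baseline keeps tracking so the
      # detector re-arms against a sustained power change
      push(p[i]); i <- i + 1L; next
    }
    if (run_len > 0L) {
      if (p[i] > cfg$threshold_k * run_base) {
        run_len <- run_len + 1L
        if (run_len == cfg$n_consecutive) {
          det_t <- c(det_t, run_t0)
          det_b <- c(det_b, run_base)
          refrac_until <- ti + cfg$epoch_s + cfg$refractory_s
          run_len <- 0L
        }
        i <- i + 1L
      } else {
        run_len <- 0L   # broken run; re-examine epoch i against fresh baseline
      }
      next
    }
    if (bn < n_base) { push(p[i]); i <- i + 1L; next }
    base <- bsum / n_base
    if (p[i] > cfg$threshold_k * base) {
      run_len <- 1L; run_t0 <- ti; run_base <- base
    } else {
      push(p[i])
    }
    i <- i + 1L
  }

  out <- data.frame(t_detect_s = det_t, baseline_power = det_b)
  class(out) <- c("detections", "data.frame")
  out
}

#' Evaluate detections against ground-truth seizure annotations
#'
#' A detection is a true positive when `t_detect_s` falls in
#' `[onset, onset + tolerance_s]` of a truth event; events and detections
#' are matched greedily in time order and each truth event is matched at
#' most once.
#'
#' @param detections output of [detect_onsets()].
#' @param truth a [seizure_events()] table.
#' @param tolerance_s matching tolerance (s), > 0.
#' @param duration_s total analyzed duration (s), used for the
#'   false-detection rate.
#' @return list with `sensitivity`, `false_detections_per_hour`,
#'   `median_latency_s`, `n_true_positive`, `n_false`.
#' @export
detection_metrics <- function(detections, truth, tolerance_s, duration_s) {
  check_scalar_num(tolerance_s, "tolerance_s", lo = 0, open_lo = TRUE)
  check_scalar_num(duration_s, "duration_s", lo = 0, open_lo = TRUE)
  dt <- sort(detections$t_detect_s)
  used <- rep(FALSE, length(dt))
  lat <- numeric()
  for (k in seq_len(nrow(truth))) {
    on <- truth$onset_s[k]
    j <- which(!used & dt >= on & dt <= on + tolerance_s)
    if (length(j)) {
      j <- j[1L]
      used[j] <- TRUE
      lat <- c(lat, dt[j] - on)
    }
  }
  n_tp <- sum(used)
  list(sensitivity = if (nrow(truth)) n_tp / nrow(truth) else NA_real_,
       false_detections_per_hour = (length(dt) - n_tp) / (duration_s / 3600),
       median_latency_s = if (length(lat)) stats::median(lat) else NA_real_,
       n_true_positive = n_tp,
       n_false = length(dt) - n_tp)
}
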