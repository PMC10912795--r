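# Peri-ictal segmentation and Welch band-power estimation.

#' Peri-ictal segmentation windows
#'
#' Defaults follow the standard peri-ictal design: pre-ictal = 30 s before
#' electrographic onset, ictal = first 5 s after onset, post-ictal = 30 s
#' after termination of the ictal discharges.
#'
#' @param pre_s,ictal_s,post_s window lengths in seconds, all > 0.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(pre_s = 30, ictal_s = 5, post_s = 30) {
  check_scalar_num(pre_s, "pre_s", lo = 0, open_lo = TRUE)
  check_scalar_num(ictal_s, "ictal_s", lo = 0, open_lo = TRUE)
  check_scalar_num(post_s, "post_s", lo = 0, open_lo = TRUE)
  structure(list(pre_s = pre_s, ictal_s = ictal_s, post_s = post_s),
            class = "segmentation_config")
}

#' Cut pre-ictal / ictal / post-ictal segments around one seizure
#'
#' Windows are half-open: pre `[onset - pre_s, onset)`, ictal
#' `[onset, onset + ictal_s)`, post `[termination, termination + post_s)`,
#' so pre never includes ictal samples. A window extending past either
#' recording boundary raises a boundary error (the pipeline skips such
#' seizures with a warning rather than truncating).
#'
#' @param rec an [recording()].
#' @param event one row of a [seizure_events()] table (or a list with
#'   `onset_s` and `termination_s`).
#' @param cfg a [segmentation_config()].
#' @return named list of `lfp_recording` segments: `pre`, `ictal`, `post`.
#' @export
segment_around_seizure <- function(rec, event, cfg = segmentation_config()) {
  on <- event$onset_s; te <- event$termination_s
  lo <- on - cfg$pre_s; hi <- te + cfg$post_s
  if (lo < rec$t0 - 1e-9 || hi > rec$t0 + rec_duration(rec) + 1e-9)
    stop_lfpdbs(sprintf(
      "peri-ictal windows [%g, %g) extend past the recording", lo, hi),
      "lfpdbs_boundary_error")
  list(pre   = slice_recording(rec, lo, on),
       ictal = slice_recording(rec, on, on + cfg$ictal_s),
       post  = slice_recording(rec, te, te + cfg$post_s))
}

#' Welch estimator configuration
#'
#' `window_s = NULL` (the default) uses one fifth of the analyzed segment —
#' 6 s windows on 30 s peri-ictal segments, 1 s on the 5 s ictal segment —
#' with 90% overlap and a Hamming taper. A sub-second analysis window
#' cannot resolve the delta band, so the window scales with the segment
#' instead of being fixed.
#'
#' @param window_s taper window length (s), or `NULL` for segment/5.
#' @param overlap_frac fractional overlap in `[0, 1)`; default 0.9.
#' @return a `welch_config` list.
#' @export
welch_config <- function(window_s = NULL, overlap_frac = 0.9) {
  if (!is.null(window_s))
    check_scalar_num(window_s, "window_s", lo = 0, open_lo = TRUE)
  check_scalar_num(overlap_frac, "overlap_frac", lo = 0, hi = 1,
                   open_hi = TRUE)
  structure(list(window_s = window_s, overlap_frac = overlap_frac),
            class = "welch_config")
}

hamming_win <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Tapered, overlapped window FFTs. Returns list(freqs, specs) where specs is
# a complex matrix (freq bin x window) of scaled FFT coefficients such that
# averaging |specs|^2 (with one-sided doubling) yields the Welch density.
welch_windows <- function(x, fs, wcfg) {
  nwin <- round((if (is.null(wcfg$window_s)) length(x) / fs / 5
                 else wcfg$window_s) * fs)
  if (nwin < 2L || nwin > length(x))
    stop_lfpdbs("Welch window must have >= 2 samples and fit the segment",
                "lfpdbs_validation_error")
  hop <- max(1L, round(nwin * (1 - wcfg$overlap_frac)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- hamming_win(nwin)
  U <- sum(w^2)
  half <- nwin %/% 2L
  specs <- vapply(starts, function(s) {
    X <- stats::fft(w * x[s:(s + nwin - 1L)])
    X[1:(half + 1L)] / sqrt(fs * U)
  }, complex(half + 1L))
  specs <- matrix(specs, nrow = half + 1L)
  list(freqs = (0:half) * fs / nwin, specs = specs, nwin = nwin)
}

onesided_scale <- function(nfreq, nwin) {
  sc <- rep(2, nfreq)
  sc[1L] <- 1
  if (nwin %% 2L == 0L) sc[nfreq] <- 1
  sc
}

#' Welch power spectral density
#'
#' Averaged one-sided periodograms of Hamming-tapered, overlapped windows.
#' The density is normalized so that its integral over `[0, fs/2]` equals
#' the segment variance (Parseval, up to taper bias); the segment mean is
#' removed first.
#'
#' @param x an [recording()] (all channels estimated) or a numeric vector.
#' @param wcfg a [welch_config()].
#' @param fs sampling rate, required when `x` is a bare vector.
#' @return object of class `psd_result`: list with `freqs` (Hz) and
#'   `density` (uV^2/Hz matrix, one column per channel), plus `fs`.
#' @examples
#' x <- sin(2 * pi * 10 * (0:29999) / 1000)
#' psd <- welch_psd(x, welch_config(), fs = 1000)
#' band_power(psd, band_def("theta", 8, 12))  # ~ 0.5 = A^2/2
#' @export
welch_psd <- function(x, wcfg = welch_config(), fs = NULL) {
  if (inherits(x, "lfp_recording")) {
    fs <- x$fs
    channels <- x$channels
    xs <- x$samples
  } else {
    if (is.null(fs)) stop_lfpdbs("fs required for vector input",
                                 "lfpdbs_validation_error")
    xs <- matrix(as.numeric(x), ncol = 1L)
    channels <- "x"
  }
  dens <- NULL; freqs <- NULL
  for (j in seq_len(ncol(xs))) {
    v <- xs[, j] - mean(xs[, j])
    ww <- welch_windows(v, fs, wcfg)
    p <- rowMeans(abs(ww$specs)^2) * onesided_scale(length(ww$freqs), ww$nwin)
    if (is.null(dens)) {
      freqs <- ww$freqs
      dens <- matrix(0, length(freqs), ncol(xs))
    }
    dens[, j] <- p
  }
  colnames(dens) <- channels
  structure(list(freqs = freqs, density = dens, fs = fs),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d frequency bins, df = %.4g Hz, channels: %s\n",
              length(x$freqs), diff(x$freqs[1:2]),
              paste(colnames(x$density), collapse = ", ")))
  invisible(x)
}

#' @export
plot.psd_result <- function(x, channel = 1L, xlim = NULL, log = "y", ...) {
  d <- x$density[, channel]
  graphics::plot(x$freqs, pmax(d, .Machine$double.xmin), type = "l",
                 log = log, xlab = "frequency (Hz)",
                 ylab = expression(paste("PSD (", mu, V^2, "/Hz)")),
                 xlim = xlim, ...)
  invisible(x)
}

# Integral of the piecewise-linear density over [a, b] (trapezoid with
# interpolated endpoints). Exactly additive over adjacent bands.
integrate_pl <- function(freqs, dens, a, b) {
  a <- max(a, freqs[1L]); b <- min(b, freqs[length(freqs)])
  if (b <= a) return(0)
  da <- stats::approx(freqs, dens, a)$y
  db <- stats::approx(freqs, dens, b)$y
  inner <- freqs > a & freqs < b
  xs <- c(a, freqs[inner], b)
  ys <- c(da, dens[inner], db)
  sum(diff(xs) * (utils::head(ys, -1L) + ys[-1L]) / 2)
}

#' Band power from a PSD
#'
#' Integral of the (piecewise-linear) density over `[f_lo, f_hi)`. By
#' construction the integral is exactly additive over adjacent bands, so a
#' partition of the frequency axis recovers the total power.
#'
#' @param psd a [welch_psd()] result.
#' @param band a [band_def()].
#' @param channel channel label or index; default 1.
#' @return band power in uV^2.
#' @export
band_power <- function(psd, band, channel = 1L) {
  if (band$f_lo >= psd$freqs[length(psd$freqs)])
    stop_lfpdbs("band lies outside the PSD frequency grid",
                "lfpdbs_validation_error")
  integrate_pl(psd$freqs, psd$density[, channel], band$f_lo, band$f_hi)
}

#' Post-/pre-ictal ratio table
#'
#' Pairs matching pre and post records per (seizure, channel, band, metric)
#' and returns their ratio post/pre. Rows with `pre == 0` are dropped with
#' a warning; a pre without a post (or vice versa) is a pairing error.
#'
#' @param records data.frame with columns `seizure_id`, `period`
#'   (containing values `"pre"` and `"post"`), `channel`, `band`, `value`
#'   (and optionally `metric`).
#' @return data.frame with one row per pair and a `ratio` column.
#' @export
post_pre_ratio <- function(records) {
  if (!"metric" %in% names(records)) records$metric <- "value"
  keys <- c("seizure_id", "channel", "band", "metric")
  pre <- records[records$period == "pre", c(keys, "value")]
  post <- records[records$period == "post", c(keys, "value")]
  names(pre)[names(pre) == "value"] <- "pre"
  names(post)[names(post) == "value"] <- "post"
  m <- merge(pre, post, by = keys, all = TRUE)
  if (anyNA(m$pre) || anyNA(m$post))
    stop_lfpdbs("unmatched pre/post records", "lfpdbs_pairing_error")
  zero <- m$pre == 0
  if (any(zero)) {
    warning(sprintf("%d record(s) with zero pre-ictal value dropped",
                    sum(zero)))
    m <- m[!zero, , drop = FALSE]
  }
  m$ratio <- m$post / m$pre
  m[order(m$seizure_id, m$channel, m$band, m$metric), ]
}
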