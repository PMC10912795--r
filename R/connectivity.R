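# Inter-regional coherence and phase-amplitude coupling.
#
# Coherence is the Welch-based magnitude-squared coherence
# |S_xy|^2 / (S_xx S_yy). Phase-amplitude coupling uses the Tort
# modulation index: instantaneous phase of the slow band (zero-phase
# band-pass then analytic signal) is binned into eighteen 20-degree
# intervals, the mean fast-band envelope per bin is normalized into a
# distribution P, and MI is the normalized Kullback-Leibler divergence of P
# from uniform, (log N - H(P)) / log N, in [0, 1].

#' Magnitude-squared coherence between two channels
#'
#' Welch cross- and auto-spectra on a common window grid. At least two
#' windows are required: the coherence of a single window is identically 1
#' and carries no information, so that configuration is rejected.
#'
#' The MSC estimator is biased upward by roughly the reciprocal of the
#' effective (independent) window count, so coherence benefits from more,
#' shorter windows than power estimation does: when `wcfg$window_s` is
#' `NULL` the coherence default is one tenth of the segment (3 s on a 30 s
#' segment, 0.33 Hz resolution), not the PSD default of one fifth.
#'
#' @param x,y equal-length numeric vectors, or a 2-column matrix in `x`.
#' @param fs sampling rate (Hz).
#' @param wcfg a [welch_config()].
#' @return object of class `coherence_spectrum`: list with `freqs` and
#'   `msc` in `[0, 1]`.
#' @export
msc <- function(x, y = NULL, fs, wcfg = welch_config()) {
  if (is.null(y)) { y <- x[, 2L]; x <- x[, 1L] }
  if (length(x) != length(y))
    stop_lfpdbs("x and y must have equal length", "lfpdbs_validation_error")
  if (is.null(wcfg$window_s)) wcfg$window_s <- length(x) / fs / 10
  wx <- welch_windows(x - mean(x), fs, wcfg)
  wy <- welch_windows(y - mean(y), fs, wcfg)
  if (ncol(wx$specs) < 2L)
    stop_lfpdbs("coherence requires at least 2 Welch windows",
                "lfpdbs_validation_error")
  sxx <- rowMeans(abs(wx$specs)^2)
  syy <- rowMeans(abs(wy$specs)^2)
  sxy <- rowMeans(wx$specs * Conj(wy$specs))
  co <- Mod(sxy)^2 / (sxx * syy)
  co[!is.finite(co)] <- 0
  structure(list(freqs = wx$freqs, msc = pmin(pmax(co, 0), 1)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d bins, df = %.4g Hz, mean MSC = %.3f\n",
              length(x$freqs), diff(x$freqs[1:2]), mean(x$msc)))
  invisible(x)
}

#' @export
plot.coherence_spectrum <- function(x, xlim = NULL, ...) {
  graphics::plot(x$freqs, x$msc, type = "l", ylim = c(0, 1), xlim = xlim,
                 xlab = "frequency (Hz)", ylab = "magnitude-squared coherence",
                 ...)
  invisible(x)
}

#' Band-averaged coherence
#' @param cs a [msc()] result.
#' @param band a [band_def()].
#' @return mean MSC over the band's frequency bins.
#' @export
band_coherence <- function(cs, band) {
  sel <- cs$freqs >= band$f_lo & cs$freqs < band$f_hi
  if (!any(sel))
    stop_lfpdbs("band contains no coherence bins", "lfpdbs_validation_error")
  mean(cs$msc[sel])
}

# Zero-phase FFT band-pass with raised-cosine transition bands and
# mirror-padding against edge wrap-around.
bandpass_fft <- function(x, fs, f_lo, f_hi, trans = NULL) {
  if (f_hi >= fs / 2)
    stop_lfpdbs("band edge at or above Nyquist", "lfpdbs_validation_error")
  if (f_hi <= f_lo)
    stop_lfpdbs("band too narrow for the filter", "lfpdbs_filter_error")
  if (is.null(trans)) trans <- max(0.5, 0.1 * (f_hi - f_lo))
  tlo <- min(trans, f_lo)            # lower transition cannot cross 0 Hz
  n <- length(x)
  npad <- min(n, ceiling(2 * fs / max(f_lo, 0.5)))
  xp <- c(rev(x[1:npad]), x, rev(x[(n - npad + 1L):n]))
  m <- length(xp)
  f <- seq(0, m - 1) / m * fs
  f <- pmin(f, fs - f)
  H <- numeric(m)
  H[f >= f_lo & f <= f_hi] <- 1
  rl <- f >= f_lo - tlo & f < f_lo
  H[rl] <- 0.5 * (1 + cos(pi * (f_lo - f[rl]) / tlo))
  rh <- f > f_hi & f <= f_hi + trans
  H[rh] <- 0.5 * (1 + cos(pi * (f[rh] - f_hi) / trans))
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / m
  y[(npad + 1L):(npad + n)]
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited component
#'
#' Zero-phase band-pass (FFT filter with raised-cosine transitions and
#' mirror padding) followed by the analytic-signal angle. The first and
#' last `edge_trim_s` seconds are discarded to suppress residual filter
#' transients.
#'
#' @param x numeric samples.
#' @param fs sampling rate (Hz).
#' @param band a [band_def()] within the Nyquist range.
#' @param edge_trim_s trim at each end (s); default 1.
#' @param trans transition bandwidth (Hz); default scales with the band.
#' @return phase series in radians, wrapped to `[-pi, pi)`.
#' @export
extract_phase <- function(x, fs, band, edge_trim_s = 1, trans = NULL) {
  xf <- bandpass_fft(x, fs, band$f_lo, band$f_hi, trans)
  ph <- Arg(analytic_signal(xf))
  ph[ph >= pi] <- ph[ph >= pi] - 2 * pi
  trim_edges(ph, fs, edge_trim_s)
}

#' Instantaneous amplitude envelope of a band-limited component
#'
#' As [extract_phase()], returning the analytic-signal magnitude.
#'
#' @inheritParams extract_phase
#' @return envelope series (uV).
#' @export
extract_amplitude <- function(x, fs, band, edge_trim_s = 1, trans = NULL) {
  xf <- bandpass_fft(x, fs, band$f_lo, band$f_hi, trans)
  trim_edges(Mod(analytic_signal(xf)), fs, edge_trim_s)
}

trim_edges <- function(x, fs, edge_trim_s) {
  k <- round(edge_trim_s * fs)
  if (2L * k >= length(x))
    stop_lfpdbs("edge trim removes the whole series", "lfpdbs_validation_error")
  if (k > 0L) x[(k + 1L):(length(x) - k)] else x
}

phase_bin_index <- function(phase, n_bins) {
  b <- floor((phase + pi) / (2 * pi / n_bins)) + 1L
  pmin.int(pmax.int(b, 1L), n_bins)
}

mi_from_profile <- function(P) {
  n <- length(P)
  P <- P / sum(P)
  nz <- P > 0
  H <- -sum(P[nz] * log(P[nz]))
  (log(n) - H) / log(n)
}

#' Tort phase-amplitude modulation index
#'
#' Phases are binned into `n_bins` equal intervals over `[-pi, pi)`
#' (default eighteen 20-degree bins), the mean amplitude per bin is
#' normalized to a distribution P, and
#' `MI = (log n_bins - H(P)) / log n_bins`. MI is 0 for a flat
#' phase-amplitude profile, 1 when all amplitude concentrates in one bin,
#' and is invariant to positive rescaling of the amplitude series.
#'
#' @param phase phase series in radians (`[-pi, pi)`).
#' @param amp amplitude series, same length, non-negative.
#' @param n_bins number of phase bins; default 18.
#' @return MI scalar in `[0, 1]`.
#' @export
modulation_index <- function(phase, amp, n_bins = 18) {
  if (length(phase) != length(amp))
    stop_lfpdbs("phase and amp must have equal length",
                "lfpdbs_validation_error")
  if (n_bins < 2L)
    stop_lfpdbs("n_bins must be >= 2", "lfpdbs_validation_error")
  b <- phase_bin_index(phase, n_bins)
  cnt <- tabulate(b, n_bins)
  if (any(cnt == 0L))
    stop_lfpdbs("empty phase bin: series too short for this binning",
                "lfpdbs_insufficient_data_error")
  P <- as.numeric(rowsum(amp, b)) / cnt
  mi <- mi_from_profile(P)
  stopifnot(mi >= 0, mi <= 1 + 1e-12)
  min(mi, 1)
}

#' Comodulogram configuration
#'
#' Defaults follow the standard cross-frequency grid: phase frequencies
#' 1-12 Hz in 0.5 Hz steps with a +/- 1 Hz filter around each center, and
#' amplitude frequencies 35-250 Hz in 5 Hz steps. The amplitude filter
#' half-width is `max(10, 1.5 * max(phase_freqs))` Hz so that the
#' modulation sidebands (carrier +/- phase frequency) pass the filter.
#'
#' @param phase_freqs phase-axis centers (Hz); default `seq(1, 12, 0.5)`.
#' @param amp_freqs amplitude-axis centers (Hz); default `seq(35, 250, 5)`.
#' @param phase_bw half-width of each phase band (Hz); default 1.
#' @param amp_bw half-width of each amplitude band (Hz); default as above.
#' @param n_bins phase bins; default 18.
#' @param edge_trim_s edge trim (s); default 1.
#' @param decimate_to working rate (Hz) the inputs are decimated to when
#'   sampled faster (brick-wall anti-alias then subsample); default 1000.
#' @return an `mi_config` list.
#' @export
mi_config <- function(phase_freqs = seq(1, 12, by = 0.5),
                      amp_freqs = seq(35, 250, by = 5),
                      phase_bw = 1, amp_bw = NULL, n_bins = 18,
                      edge_trim_s = 1, decimate_to = 1000) {
  if (is.null(amp_bw)) amp_bw <- max(10, 1.5 * max(phase_freqs))
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs,
                 phase_bw = phase_bw, amp_bw = amp_bw,
                 n_bins = as.integer(n_bins), edge_trim_s = edge_trim_s,
                 decimate_to = decimate_to),
            class = "mi_config")
}

decimate_for_pac <- function(x, fs, target) {
  fac <- floor(fs / target)
  if (fac < 2L) return(list(x = x, fs = fs))
  xl <- shape_spectrum(x, fs, function(f) as.numeric(f <= 0.45 * fs / fac))
  list(x = xl[seq(1L, length(xl), by = fac)], fs = fs / fac)
}

#' Phase-amplitude comodulogram
#'
#' Computes the modulation index at every (phase center, amplitude center)
#' pair of the grid. Phase and amplitude may come from the same channel
#' (within-region coupling) or different channels (inter-regional, e.g.
#' hippocampal theta phase modulating prefrontal gamma amplitude).
#'
#' @param phase_src numeric samples providing the slow phase.
#' @param amp_src numeric samples providing the fast amplitude
#'   (same length and rate).
#' @param fs sampling rate (Hz).
#' @param cfg an [mi_config()].
#' @param labels length-2 character vector naming the phase and amplitude
#'   sources.
#' @return object of class `comodulogram`: list with `phase_freqs`,
#'   `amp_freqs`, `mi` (phase x amp matrix) and `labels`.
#' @export
comodulogram <- function(phase_src, amp_src, fs, cfg = mi_config(),
                         labels = c("phase", "amp")) {
  if (length(phase_src) != length(amp_src))
    stop_lfpdbs("phase and amplitude sources must have equal length",
                "lfpdbs_validation_error")
  if (max(cfg$amp_freqs) + cfg$amp_bw >= fs / 2 &&
      max(cfg$amp_freqs) + cfg$amp_bw >= cfg$decimate_to / 2)
    stop_lfpdbs("amplitude grid exceeds the Nyquist frequency",
                "lfpdbs_validation_error")
  if (length(phase_src) / fs < 10 / min(cfg$phase_freqs))
    stop_lfpdbs("segment shorter than 10 cycles of the lowest phase frequency",
                "lfpdbs_validation_error")
  dp <- decimate_for_pac(phase_src, fs, cfg$decimate_to)
  da <- decimate_for_pac(amp_src, fs, cfg$decimate_to)
  fsw <- dp$fs
  if (max(cfg$amp_freqs) + cfg$amp_bw >= fsw / 2)
    stop_lfpdbs("amplitude grid exceeds the working Nyquist frequency",
                "lfpdbs_validation_error")

  bins <- lapply(cfg$phase_freqs, function(fc) {
    ph <- extract_phase(dp$x, fsw, band_def("p", max(fc - cfg$phase_bw, 0.2),
                                            fc + cfg$phase_bw),
                        cfg$edge_trim_s)
    phase_bin_index(ph, cfg$n_bins)
  })
  envs <- lapply(cfg$amp_freqs, function(fc)
    extract_amplitude(da$x, fsw, band_def("a", max(fc - cfg$amp_bw, 1),
                                          fc + cfg$amp_bw),
                      cfg$edge_trim_s))
  mi <- matrix(NA_real_, length(cfg$phase_freqs), length(cfg$amp_freqs))
  for (i in seq_along(bins)) {
    b <- bins[[i]]
    cnt <- tabulate(b, cfg$n_bins)
    if (any(cnt == 0L))
      stop_lfpdbs("empty phase bin in comodulogram",
                  "lfpdbs_insufficient_data_error")
    for (j in seq_along(envs)) {
      P <- as.numeric(rowsum(envs[[j]], b)) / cnt
      mi[i, j] <- mi_from_profile(P)
    }
  }
  stopifnot(all(mi >= 0), all(mi <= 1))
  structure(list(phase_freqs = cfg$phase_freqs, amp_freqs = cfg$amp_freqs,
                 mi = mi, labels = labels),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  k <- arrayInd(which.max(x$mi), dim(x$mi))
  cat(sprintf(
    "<comodulogram> %d x %d grid (%s phase x %s amplitude), max MI = %.4g at (%g Hz, %g Hz)\n",
    nrow(x$mi), ncol(x$mi), x$labels[1L], x$labels[2L], max(x$mi),
    x$phase_freqs[k[1L]], x$amp_freqs[k[2L]]))
  invisible(x)
}

#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$phase_freqs, x$amp_freqs, x$mi,
                  xlab = "phase frequency (Hz)",
                  ylab = "amplitude frequency (Hz)",
                  main = sprintf("MI: %s phase x %s amplitude",
                                 x$labels[1L], x$labels[2L]), ...)
  invisible(x)
}

#' Band-level modulation index
#'
#' Single band-wide filters (e.g. theta phase 4-12 Hz against gamma
#' amplitude 50-250 Hz) rather than the comodulogram's narrow-band grid.
#'
#' @param phase_src,amp_src equal-length numeric sample vectors.
#' @param fs sampling rate (Hz).
#' @param phase_band,amp_band [band_def()]s for the slow and fast bands.
#' @param n_bins phase bins; default 18.
#' @param edge_trim_s edge trim (s); default 1.
#' @return MI scalar.
#' @export
band_mi <- function(phase_src, amp_src, fs, phase_band, amp_band,
                    n_bins = 18, edge_trim_s = 1) {
  ph <- extract_phase(phase_src, fs, phase_band, edge_trim_s)
  am <- extract_amplitude(amp_src, fs, amp_band, edge_trim_s)
  modulation_index(ph, am, n_bins)
}
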