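# Synthetic two-channel LFP generator.
#
# Every downstream stage (detection, stimulation, spectral, coupling,
# statistics) is tested against signals produced here, because the generator
# carries exact ground truth: spectral slope and rms of the background,
# per-band oscillation power, the modulation depth of the phase-amplitude
# coupled component, the shared-source mixing weight that fixes the expected
# coherence in closed form, and the exact seizure schedule.

#' Generate 1/f^alpha background noise
#'
#' Gaussian white noise is shaped in the frequency domain by `f^(-alpha/2)`
#' (the DC bin is zeroed) and rescaled so the sample rms equals `rms`
#' exactly. `alpha = 0` gives white noise; `alpha = 1` pink; `alpha = 2`
#' brown. The average periodogram then has log-log slope `-alpha`.
#'
#' @param duration_s length in seconds.
#' @param fs sampling rate (Hz).
#' @param alpha spectral exponent in `[0, 2]`.
#' @param rms target root-mean-square amplitude (uV), > 0.
#' @param seed integer seed; the same seed reproduces the series bit for bit.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @export
gen_background <- function(duration_s, fs, alpha = 1, rms = 50, seed = 1) {
  check_scalar_num(duration_s, "duration_s", lo = 0, open_lo = TRUE)
  check_scalar_num(fs, "fs", lo = 0, open_lo = TRUE)
  check_scalar_num(alpha, "alpha", lo = 0, hi = 2)
  check_scalar_num(rms, "rms", lo = 0, open_lo = TRUE)
  n <- round(duration_s * fs)
  with_seed(seed, {
    w <- stats::rnorm(n)
    x <- shape_spectrum(w, fs, function(f) ifelse(f > 0, f^(-alpha / 2), 0))
    x <- x - mean(x)
    x * rms / sqrt(mean(x^2))
  })
}

# Multiply the spectrum of real series x by gain(f); returns a real series.
shape_spectrum <- function(x, fs, gain) {
  n <- length(x)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)          # fold to [0, fs/2]
  g <- gain(f)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# Band-limited Gaussian noise, exact rms, via brick-wall spectral masking.
gen_bandlimited <- function(duration_s, fs, f_lo, f_hi, rms, seed) {
  n <- round(duration_s * fs)
  with_seed(seed, {
    w <- stats::rnorm(n)
    x <- shape_spectrum(w, fs, function(f) as.numeric(f >= f_lo & f <= f_hi))
    x <- x - mean(x)
    x * rms / sqrt(mean(x^2))
  })
}

#' Generate a phase-amplitude coupled test signal
#'
#' Constructs the standard amplitude-modulated-carrier model of
#' cross-frequency coupling:
#' `s(t) = A(t) sin(2 pi f_amp t) + sin(2 pi f_phase t) + eps(t)` with
#' envelope `A(t) = carrier_rms (1 + chi sin(2 pi f_phase t)) / (1 + chi)`.
#' The modulation depth of the fast carrier's envelope therefore equals
#' `chi` by construction: `chi = 0` gives a constant envelope (no coupling)
#' and `chi = 1` full modulation, which is what the modulation-index
#' recovery tests exploit.
#'
#' @param f_phase slow (phase-providing) frequency, Hz.
#' @param f_amp fast (amplitude-providing) frequency, Hz; must satisfy
#'   `f_phase < f_amp < fs/2`.
#' @param depth modulation depth `chi` in `[0, 1]`.
#' @param carrier_rms scale of the fast carrier envelope (uV).
#' @param duration_s,fs,seed as in [gen_background()].
#' @param noise_rms rms of the additive white noise term (uV); default 0.1.
#' @return numeric vector of samples.
#' @export
gen_pac_signal <- function(f_phase, f_amp, depth, carrier_rms = 1,
                           duration_s = 30, fs = 1000, seed = 1,
                           noise_rms = 0.1) {
  check_scalar_num(depth, "depth", lo = 0, hi = 1)
  check_scalar_num(f_phase, "f_phase", lo = 0, open_lo = TRUE)
  if (f_amp >= fs / 2)
    stop_lfpdbs("f_amp must be below the Nyquist frequency fs/2",
                "lfpdbs_nyquist_error")
  if (f_amp <= f_phase)
    stop_lfpdbs("f_amp must exceed f_phase", "lfpdbs_validation_error")
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  env <- carrier_rms * (1 + depth * sin(2 * pi * f_phase * t)) / (1 + depth)
  x <- env * sin(2 * pi * f_amp * t) + sin(2 * pi * f_phase * t)
  if (noise_rms > 0)
    x <- x + with_seed(seed, stats::rnorm(n, sd = noise_rms))
  x
}

#' Generate a pair of channels with controlled coherence
#'
#' Both channels mix one shared band-limited source `s` with an independent
#' band-limited noise of equal power:
#' `y_i = lambda s + sqrt(1 - lambda^2) n_i`. Within the band the
#' magnitude-squared coherence between the channels is `lambda^4` in
#' closed form (cross-spectrum `lambda^2 S`, auto-spectra `S`), which the
#' coherence estimator tests use as their analytic target.
#'
#' @param lambda shared-component mixing weight in `[0, 1]`.
#' @param band a [band_def()] giving the common passband.
#' @param rms per-channel rms (uV).
#' @param duration_s,fs,seed as in [gen_background()].
#' @return two-column matrix (one column per channel).
#' @export
gen_coherent_pair <- function(lambda, band, rms = 20, duration_s = 30,
                              fs = 1000, seed = 1) {
  check_scalar_num(lambda, "lambda", lo = 0, hi = 1)
  s  <- gen_bandlimited(duration_s, fs, band$f_lo, band$f_hi, rms,
                        substream_seed(seed, 101))
  n1 <- gen_bandlimited(duration_s, fs, band$f_lo, band$f_hi, rms,
                        substream_seed(seed, 102))
  n2 <- gen_bandlimited(duration_s, fs, band$f_lo, band$f_hi, rms,
                        substream_seed(seed, 103))
  cbind(lambda * s + sqrt(1 - lambda^2) * n1,
        lambda * s + sqrt(1 - lambda^2) * n2)
}

#' Specification of a synthetic two-channel LFP recording
#'
#' Collects all generator parameters; [assemble_recording()] turns it into a
#' recording plus ground-truth seizure annotations. Components are summed
#' per channel: 1/f background, band-limited oscillations, an optional
#' phase-amplitude coupled component on one channel, and an optional shared
#' band-limited source that induces inter-channel coherence. Within each
#' scheduled seizure the background ("broadband") component is multiplied by
#' `sqrt(broadband_gain)` — so its power increases by `broadband_gain` — and
#' a periodic spike-wave train is added.
#'
#' @param duration_s total duration (s).
#' @param fs sampling rate (Hz); default 10000, the assumed acquisition rate.
#' @param seed master integer seed; per-component substreams derive from it.
#' @param channels two channel labels; default `c("HC", "mPFC")`.
#' @param background list `(alpha, rms)` of the 1/f component.
#' @param oscillations list of lists `(band, rms)`; independent band-limited
#'   noise per channel.
#' @param pac `NULL` or list `(f_phase, f_amp, depth, carrier_rms, channel)`.
#' @param pair_coupling `NULL` or list `(lambda, band, rms)` shared source.
#' @param seizures `NULL` or data.frame with columns `onset_s`, `duration_s`
#'   and optional `broadband_gain` (power gain, >= 1, default 10),
#'   `spikewave_hz` (default 3), `spike_rms` (uV, default 200).
#' @param artifact list `(a0, tau_s)` stimulation artifact shape used by
#'   [inject_artifacts()]; amplitude a0 in uV, decay time constant in s.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(duration_s, fs = 10000, seed = 1,
                       channels = c("HC", "mPFC"),
                       background = list(alpha = 1, rms = 50),
                       oscillations = list(),
                       pac = NULL,
                       pair_coupling = NULL,
                       seizures = NULL,
                       artifact = list(a0 = 500, tau_s = 0.003)) {
  check_scalar_num(duration_s, "duration_s", lo = 0, open_lo = TRUE)
  check_scalar_num(fs, "fs", lo = 0, open_lo = TRUE)
  if (!is.null(pac)) check_scalar_num(pac$depth, "pac$depth", lo = 0, hi = 1)
  if (!is.null(pair_coupling))
    check_scalar_num(pair_coupling$lambda, "pair_coupling$lambda", lo = 0, hi = 1)
  if (!is.null(seizures) && nrow(seizures)) {
    seizures <- as.data.frame(seizures)
    if (is.null(seizures$broadband_gain)) seizures$broadband_gain <- 10
    if (is.null(seizures$spikewave_hz)) seizures$spikewave_hz <- 3
    if (is.null(seizures$spike_rms)) seizures$spike_rms <- 200
    if (any(seizures$broadband_gain < 1))
      stop_lfpdbs("broadband_gain must be >= 1", "lfpdbs_validation_error")
    o <- order(seizures$onset_s)
    seizures <- seizures[o, , drop = FALSE]
    ends <- seizures$onset_s + seizures$duration_s
    if (any(seizures$onset_s < 0) || any(ends > duration_s))
      stop_lfpdbs("seizures must lie inside [0, duration_s)",
                  "lfpdbs_validation_error")
    if (nrow(seizures) > 1L &&
        any(seizures$onset_s[-1L] < ends[-nrow(seizures)]))
      stop_lfpdbs("seizure intervals must not overlap", "lfpdbs_validation_error")
  }
  structure(list(duration_s = duration_s, fs = fs, seed = as.integer(seed),
                 channels = channels, background = background,
                 oscillations = oscillations, pac = pac,
                 pair_coupling = pair_coupling, seizures = seizures,
                 artifact = artifact),
            class = "synth_spec")
}

# Raised-cosine spike-wave train at `rate` Hz inside [0, dur), rms-scaled.
spikewave_train <- function(dur, fs, rate, rms) {
  n <- round(dur * fs)
  x <- numeric(n)
  width <- max(3L, round(0.025 * fs))          # 25 ms transient
  shape <- (1 - cos(2 * pi * seq_len(width) / (width + 1))) / 2
  shape <- shape^3                              # sharpen into a spike
  onsets <- seq(0, dur - 1 / rate, by = 1 / rate)
  for (t0 in onsets) {
    i0 <- round(t0 * fs)
    idx <- (i0 + 1):min(i0 + width, n)
    x[idx] <- x[idx] + shape[seq_along(idx)]
  }
  if (all(x == 0)) return(x)
  x * rms / sqrt(mean(x^2))
}

#' Assemble a synthetic recording from a specification
#'
#' Deterministic given `(spec, spec$seed)`. Returns both the recording and
#' the ground-truth seizure annotations (exactly the scheduled intervals,
#' Racine score 4 — behavior is not simulated).
#'
#' @param spec a [synth_spec()].
#' @return list with elements `recording` (an `lfp_recording`) and
#'   `events` (a `seizure_events` data.frame).
#' @examples
#' sp <- synth_spec(duration_s = 10, fs = 500, seed = 42,
#'                  background = list(alpha = 1, rms = 30))
#' out <- assemble_recording(sp)
#' out$recording
#' @export
assemble_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$duration_s * spec$fs)
  nc <- length(spec$channels)
  x <- matrix(0, n, nc)

  # broadband background, per channel; seizure gain applies to this component
  bg <- sapply(seq_len(nc), function(j)
    gen_background(spec$duration_s, spec$fs, spec$background$alpha,
                   spec$background$rms, substream_seed(spec$seed, j)))
  if (!is.null(spec$seizures) && nrow(spec$seizures)) {
    t <- (0:(n - 1)) / spec$fs
    for (k in seq_len(nrow(spec$seizures))) {
      sz <- spec$seizures[k, ]
      idx <- which(in_interval(t, sz$onset_s, sz$onset_s + sz$duration_s))
      bg[idx, ] <- bg[idx, ] * sqrt(sz$broadband_gain)
      train <- spikewave_train(sz$duration_s, spec$fs, sz$spikewave_hz,
                               sz$spike_rms)
      for (j in seq_len(nc))
        x[idx, j] <- x[idx, j] + train[seq_along(idx)]
    }
  }
  x <- x + bg

  for (i in seq_along(spec$oscillations)) {
    osc <- spec$oscillations[[i]]
    for (j in seq_len(nc))
      x[, j] <- x[, j] + gen_bandlimited(
        spec$duration_s, spec$fs, osc$band$f_lo, osc$band$f_hi, osc$rms,
        substream_seed(spec$seed, 10L * i + j))
  }

  if (!is.null(spec$pac)) {
    ch <- if (is.null(spec$pac$channel)) 1L else
      match(spec$pac$channel, spec$channels)
    crms <- if (is.null(spec$pac$carrier_rms)) 1 else spec$pac$carrier_rms
    x[, ch] <- x[, ch] + gen_pac_signal(
      spec$pac$f_phase, spec$pac$f_amp, spec$pac$depth, crms,
      spec$duration_s, spec$fs, substream_seed(spec$seed, 900),
      noise_rms = 0)
  }

  if (!is.null(spec$pair_coupling)) {
    pc <- spec$pair_coupling
    rms <- if (is.null(pc$rms)) 20 else pc$rms
    pair <- gen_coherent_pair(pc$lambda, pc$band, rms, spec$duration_s,
                              spec$fs, substream_seed(spec$seed, 950))
    x[, 1L] <- x[, 1L] + pair[, 1L]
    x[, 2L] <- x[, 2L] + pair[, 2L]
  }

  ev <- if (!is.null(spec$seizures) && nrow(spec$seizures))
    seizure_events(spec$seizures$onset_s,
                   spec$seizures$onset_s + spec$seizures$duration_s,
                   rep(4L, nrow(spec$seizures)))
  else seizure_events()

  list(recording = recording(x, fs = spec$fs, channels = spec$channels),
       events = ev)
}
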