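# Independent oracle implementations used to cross-check the package's
# estimators. These deliberately share no code with R/.

# Brute-force Tort modulation index: explicit per-bin subsetting and
# entropy, no shared binning code.
oracle_mi <- function(phase, amp, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    sel <- phase >= edges[j] & phase < edges[j + 1L]
    if (!any(sel)) stop("empty bin in oracle")
    means[j] <- mean(amp[sel])
  }
  P <- means / sum(means)
  H <- -sum(ifelse(P > 0, P * log(P), 0))
  (log(n_bins) - H) / log(n_bins)
}

# Quadrature-pair phase oracle: an independently constructed 90-degree
# phase shifter (multiply positive frequencies by -i, negative by +i),
# then the four-quadrant arctangent.
oracle_quadrature_phase <- function(xf) {
  n <- length(xf)
  X <- fft(xf)
  k <- 0:(n - 1)
  sgn <- ifelse(k == 0 | (n %% 2 == 0 & k == n / 2), 0,
                ifelse(k < n / 2, -1, 1))
  xh <- Re(fft(X * 1i * sgn, inverse = TRUE)) / n
  atan2(xh, xf)
}

# Brute-force epoch power: explicit loop.
oracle_epoch_power <- function(x, fs, epoch_s) {
  spl <- round(epoch_s * fs)
  nep <- length(x) %/% spl
  vapply(seq_len(nep), function(i)
    mean(x[((i - 1L) * spl + 1L):(i * spl)]^2), numeric(1))
}

# Brute-force detection/truth matcher: each truth event takes the first
# unused detection inside its tolerance window.
oracle_match <- function(det_t, truth_onsets, tol) {
  used <- rep(FALSE, length(det_t))
  tp <- 0L
  for (on in sort(truth_onsets)) {
    j <- which(!used & det_t >= on & det_t <= on + tol)
    if (length(j)) { used[j[1L]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = sum(!used))
}

# Small two-channel noise recording for IO tests.
make_noise_recording <- function(duration_s = 1, fs = 1000, seed = 1,
                                 channels = c("HC", "mPFC")) {
  set.seed(seed)
  recording(matrix(rnorm(round(duration_s * fs) * length(channels), sd = 50),
                   ncol = length(channels)),
            fs = fs, channels = channels)
}
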