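---
title: "Closed-loop DBS simulation and peri-ictal LFP analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop DBS simulation and peri-ictal LFP analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpdbs)
```

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open.

## Conventions

Time is in seconds, amplitudes in microvolts (µV), power in µV² and
spectral density in µV²/Hz. Samples are 0-based and every interval —
slices, epochs, peri-ictal windows, exclusion and blanking windows — is
half-open `[start, end)`, which makes adjacent windows partition samples
exactly (no double counting at boundaries). Recordings are stored as EDF:
a 16-bit format, so one write/read round trip quantizes each channel to
its absolute maximum divided by 32767. The assumed acquisition rate for
in-vivo material is 10 kHz; the examples and tests in this package run at
250–2000 Hz, which keeps runtimes in seconds while leaving every band of
interest (≤ 250 Hz) far below Nyquist.

## The synthetic-data generator

`synth_spec()` + `assemble_recording()` produce two-channel recordings as
a sum of independently seeded components, each with a closed-form ground
truth:

* **1/f^α background** (`gen_background`): Gaussian white noise shaped in
  the frequency domain by f^(−α/2) and rescaled to an exact sample rms.
  Default α = 1 (pink), rms 50 µV — representative magnitudes for rodent
  hippocampal LFP. The average periodogram slope is −α by construction.
* **Band-limited oscillations**: brick-wall filtered Gaussian noise per
  band, exact rms, independent across channels.
* **Phase–amplitude coupling** (`gen_pac_signal`): the standard
  amplitude-modulated carrier
  `s(t) = A(t) sin(2π f_amp t) + sin(2π f_phase t)`,
  `A(t) = c (1 + χ sin(2π f_phase t)) / (1 + χ)`. The envelope's
  modulation depth equals χ exactly, which is what the recovery tests
  need. The field's analyses *measure* coupling; this constructive form
  exists only to provide ground truth.
* **Inter-channel coherence** (`gen_coherent_pair`):
  `y_i = λ s + sqrt(1 − λ²) n_i` with `s`, `n_i` independent equal-power
  band-limited noises. The in-band magnitude-squared coherence is λ⁴ in
  closed form (cross-spectrum λ²S over auto-spectra S), giving the
  coherence estimator an analytic target.
* **Seizures**: inside each scheduled interval the background component is
  multiplied by `sqrt(g)` (so its *power* gains a factor `g`) and a
  raised-cosine spike-wave train (default 3 Hz, rms-scaled) is added.
  Ground-truth annotations are exactly the scheduled intervals; the
  behavioral score is fixed at 4 because behavior is not simulated.
* **Stimulation artifacts**: each pulse contributes a square pulse of the
  protocol width followed by an opposite-sign exponential (default
  τ = 3 ms) whose area cancels the pulse area — the signature of passive
  charge balancing, where the electrode capacitance discharges through a
  shorting phase over a few milliseconds.

All components derive their seeds deterministically from one integer, so
a spec reproduces its recording bit for bit.

What the generator does **not** emulate: non-stationary background drift,
mains hum, electrode pops, movement artifacts, seizure evolution
(tonic–clonic morphology changes, post-ictal suppression), or behavioral
state. Tests passing on this material therefore demonstrate correctness
of the *estimators and their contracts*, not robustness to every failure
mode of chronic in-vivo recordings.

One dilution effect is worth knowing about because it is real, not an
artifact of the generator: the within-channel modulation index of an
assembled recording stays near chance even when a PAC component is
present, whenever uncoupled theta and gamma sources dominate the channel
(the extracted theta phase then follows the uncoupled theta). Group
contrasts on coupling are therefore demonstrated on signals where the
modulating rhythm dominates, and the same caveat applies to real data:
MI measures the coupling of the *extracted* phase and envelope, not of a
latent component.

## Online detection

`detect_onsets()` mirrors the classic responsive-stimulation design:
mean-square power over non-overlapping 10 ms epochs, compared against a
10 s trailing baseline, with an onset declared after 100 consecutive
epochs above `k` times the baseline. Choices and their reasons:

* **Threshold `k` = 4** is not a published constant (the original design
  refers to prior work for it); it is a config knob. For Gaussian noise a
  10 ms epoch power is χ²-distributed with mean B, and
  `P(P_epoch > 4B)` is below 0.5%, so 100 consecutive exceedances are
  effectively impossible under stationarity — the suite verifies zero
  false detections on 20 × 600 s of noise.
* **Baseline freezing.** The baseline is frozen during exclusion windows
  (stimulation episodes) and during a candidate run, so artifactual and
  early-ictal epochs never inflate it. During the post-detection
  refractory period (default 60 s) the baseline *resumes* tracking;
  otherwise a sustained power shift would re-trigger once per refractory
  period instead of being detected exactly once.
* **Back-dating.** The detection time is the *start* of the qualifying
  run, so the 5 s ictal analysis window covers the earliest ictal
  activity. A consequence: a single chance supra-threshold epoch
  immediately before the true onset can pull the detection up to a few
  epochs early, which evaluation code must tolerate.
* **Epochs are non-overlapping** (hop = epoch), the simplest reading of
  consecutive epochs; overlap is configurable.

A practical detectability note that shaped the demo conditions: for 1/f
background, single-epoch power has a heavy left tail (about 1% of 10 ms
epochs fall below ~0.09 of the mean), and the 100-consecutive-epoch rule
breaks on every such trough. A run survives with high probability only
when the ictal-to-baseline power ratio is large compared to `k` divided
by that tail quantile — hence the end-to-end demonstrations use a
broadband power gain of 100 (amplitude ×10, typical of severe
electrographic seizures). With gain near `4k` the detector still fires,
but with second-scale, heavy-tailed latency.

## Stimulation scheduling and artifact handling

The protocol constants are fixed by the printed pattern: 4 packages × 200
monophasic pulses of 0.1 ms at 1 Hz, 5 min intervals. "5 min intervals"
is ambiguous, so both readings are implemented:
`"gap-after-package-end"` (default; 300 s from last pulse to next
package) and `"start-to-start"` (package onsets 300 s apart, valid since
a package spans 199 s < 300 s). Under the default, an episode spans
4 × 199 + 3 × 300 = 1696 s.

Artifact removal is blank-and-interpolate: samples in a 10 ms window from
each pulse are replaced by linear interpolation between the bounding
samples (exact for locally affine signals, idempotent by construction).
At 1 Hz stimulation this discards 1% of the data, which is why blanking
was preferred over template subtraction; the 10 ms default covers the
0.1 ms pulse plus the few-ms discharge transient.

## Spectral estimation

`welch_psd()` averages one-sided periodograms of Hamming-tapered windows
with 90% overlap, normalized so the density integrates to the segment
variance (verified against Parseval within 5% on white noise; the segment
mean is removed once, not per window). The default window is one fifth of
the segment — 6 s on the 30 s peri-ictal windows, 1 s on the 5 s ictal
window. A fixed millisecond-scale window cannot resolve the delta band at
all, so the window scales with the segment; the 90% overlap and 30 s
segment lengths are retained as printed. `band_power()` integrates the
piecewise-linear density, which makes band powers exactly additive over a
partition of the frequency axis.

Band edges: delta is implemented as [0.5, 4) Hz — the 0.5 Hz floor is a
detrending/high-pass convention, as "< 4 Hz" has no finite lower edge —
theta [4, 12), gamma [30, 150). Gamma sub-band boundaries are not
standardized; the defaults 30–55 / 55–95 / 95–150 Hz keep 50 and 60 Hz
mains away from the boundaries. No notch filter is applied by default
(synthetic data has no hum); a notch is a preprocessing concern for real
recordings.

Peri-ictal windows are `[onset−30, onset)`, `[onset, onset+5)` and
`[termination, termination+30)`; a window that would leave the recording
raises a boundary error and the pipeline skips that seizure with a
warning, never silently truncating. Whether ictal PSDs in the source
design reused the 30 s Welch parameters is unknown; here the same
configuration applies with the window scaled to the segment.

## Coherence

`msc()` computes `|S_xy|² / (S_xx S_yy)` from Welch cross- and
auto-spectra on a common grid, and `band_coherence()` averages over band
bins. The estimator is biased upward by roughly the reciprocal of the
effective number of independent windows; at 90% overlap neighboring
windows are strongly correlated, so coherence defaults to windows of one
*tenth* of the segment (measured null bias ≈ 0.06 on 30 s segments,
versus ≈ 0.13 at one fifth) while PSD keeps the longer window for
resolution. A single-window configuration is rejected outright, since one
window gives MSC ≡ 1. Against the generator's closed form, 30 s
shared-source pairs at λ = 0.8 average within 0.03 of λ⁴ = 0.41.

## Phase–amplitude coupling

Phase and envelope come from zero-phase FFT band-pass filters
(raised-cosine transition bands, mirror padding against edge wrap) and
the analytic signal; the first and last second are trimmed to suppress
residual transients. The modulation index follows the 18-bin
entropy-based definition; it is exactly 0 for a flat phase–amplitude
profile, exactly 1 for a one-bin profile, scale-invariant in the
amplitude, and matched to an independent brute-force implementation at
1e-12. An empty phase bin raises an insufficient-data error rather than
returning a biased value.

Comodulograms use the 1–12 Hz (0.5 Hz step) phase grid and a 35–250 Hz
amplitude grid; the amplitude step (5 Hz, giving a 23 × 44 grid) is a
package default, as no step is standardized. Per grid point the phase
filter is ±1 Hz and the amplitude filter half-width is
`max(10, 1.5 × max phase frequency)` Hz so the modulation sidebands
(carrier ± modulator) pass — a narrower amplitude filter structurally
suppresses MI. Inputs sampled faster than 1 kHz are decimated (brick-wall
anti-alias, then subsampling) before filtering: the grid tops out at
250 Hz and the 67 narrow-band filterings per comodulogram are much
cheaper at 1 kHz than at 10 kHz. Band-level MI (e.g. theta phase ×
gamma amplitude, both directions between HC and mPFC and within each
channel) uses single band-wide filters. Surrogate-based significance
testing of MI is deliberately out of scope.

## Group statistics

Per-seizure metric values are treated as independent samples across
groups — the design this mirrors pools 14 + 24 + 14 + 12 ≈ 64 samples
into (3, 60)-df one-way ANOVAs. That is pseudo-replication with respect
to animals; it is documented rather than "fixed" because the package's
job is to reproduce the analysis chain. Normality screening uses the KS
statistic against a normal with estimated mean/sd with the Lilliefors
p-value (the plain KS null is badly conservative once parameters are
estimated from the sample; with it, even a uniform sample of n = 200
routinely passes). Lilliefors requires n ≥ 4. ANOVA and Tukey's HSD wrap
the standard `aov`/`TukeyHSD` machinery (Tukey–Kramer for unequal n),
with the studentized-range q reported per pair; the suite checks the
two-group F = t² identity at 1e-10, the (3, 60) df pattern, shift/scale
invariance, and a 2000-replicate null calibration of the 5% level.

## The end-to-end loop

`run_closed_loop()` alternates detection and scheduling causally: the
earliest accepted detection triggers an episode at the decision time, the
episode becomes an exclusion window (otherwise its artifacts would
re-trigger the detector), and detection resumes after the episode. The
intervention effect — stimulated seizures have their duration multiplied
by a shortening factor — is explicit bookkeeping, clearly labeled as a
simulation knob: the package provides the mechanism so before/during/after
accounting (`seizure_accounting()`) is exercisable, not a claim about
efficacy. Post-ictal windows that overlap stimulation are analyzed after
artifact removal. `run_analysis()` writes tidy CSV metric/ratio tables
plus a JSON manifest of configuration and seed; rerunning from the same
manifest reproduces every output bit for bit, and analyses are invariant
to shifting the recording's time origin.

## Problem sizes

The shipped tests and the acceptance script generate all inputs at run
time at 250–2000 Hz with segment lengths of 10–600 s, 20-seed Monte-Carlo
repetitions for stochastic checks and 2000 replicates for the ANOVA null
— sizes at which every closed-form target above is resolvable with
comfortable margins and a full run takes on the order of a minute.

## Known limitations

* EDF support covers the plain, equal-rate 16-bit layout only (no EDF+
  annotations, no mixed rates).
* The detector is single-channel and power-based by design; line-length,
  spike-morphology or learned detectors are out of scope.
* MSC and MI estimates are reported without analytical confidence
  intervals; the package's statistical layer operates on per-seizure
  samples instead.
* The spike-wave morphology is stylized (periodic raised-cosine
  transients); it produces realistic broadband power but not the
  waveform detail of real ictal discharges.
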