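---
title: "Heart-sound segmentation in heartseg: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-sound segmentation in heartseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartseg)
```

## The segmentation model

A phonocardiogram of a resting subject is modeled as a quasi-periodic
sequence of two transient bursts per cardiac cycle — S1 at the start of
systole, S2 at the start of diastole — embedded in broadband noise
(breathing, handling, ambient sound). The package's four-state labeling is
purely onset-based:

* systole = S1 onset to S2 onset,
* diastole = S2 onset to the next S1 onset.

These definitions force three structural identities that the code
maintains *exactly* rather than approximately: systolic + diastolic
duration equals cycle duration (the cycle duration is literally their
sum), S1 lies inside systole, and S2 inside diastole. A practical
consequence is that any feature defined through a maximum over the
segment (e.g. the frame-level `maxdb`) is necessarily shared between S1
and systole whenever S1 carries the systolic peak — identical S1/systolic
columns in summary tables are a structural property of the state
definitions, not a coincidence.

Key assumptions: one dominant S1-like and at most one dominant S2-like
burst per cycle; a heart rate inside a configurable 40–200 bpm band; and
enough cycles (at least two) to establish periodicity. Murmurs, S3/S4,
arrhythmia-specific logic, and learned models are out of scope.

## Detection pipeline and its parameters

1. **Standardization** — mean removal, then peak normalization to
   `max |x| = 1`. Chosen over RMS normalization so that decibel features
   read directly as dBFS (0 dB = full scale), the convention of audio
   editors' meters. Silent input is a named error, not a NaN cascade.
2. **Band-pass 25–400 Hz** — a 2nd-order Butterworth applied forward and
   backward (`signal::filtfilt`), i.e. zero-phase with an effective
   4th-order magnitude response. The band covers S1/S2 energy
   (fundamentals of healthy S1 sit near 25–120 Hz, S2 slightly higher)
   while rejecting breathing rumble and most ambient noise. Filtering is
   used *only* for detection; features are computed on the unfiltered
   standardized signal so amplitude features describe the recording, not
   the filter.
3. **Envelope** — average Shannon energy, `-x² ln x²` per sample averaged
   over 0.02 s frames with 0.01 s hop. Shannon energy is the de facto
   standard PCG envelope because it emphasizes medium-intensity
   components: weak noise is suppressed quadratically while the loudest
   samples (|x| → 1) are de-emphasized by the logarithm. The transform is
   deliberately left unnormalized so closed-form values (e.g. a constant
   `|x| = e^{-1/2}` signal has envelope `e^{-1}`) survive; all detection
   thresholds are relative.
4. **S1 peak train** (`detect_s1_peaks`) — local envelope maxima above
   `peak_rel_threshold` (default 0.2) of the envelope maximum are
   candidates; maxima closer than `max(3 × frame, 0.06 s)` are merged
   (same burst lobe). The cycle period is estimated from the envelope
   autocorrelation restricted to the heart-rate band, preferring the
   smallest lag whose autocorrelation is a local maximum within 15% of
   the best — a guard against period doubling when two periods fit the
   band. A periodic train is then chained greedily (window ±25% of the
   period) from several early anchors plus the tallest candidate, and the
   train with the most regular intervals (minimum coefficient of
   variation of inter-peak gaps) wins.

   Two non-obvious choices deserve explanation:

   * *Which train is S1?* The S1 and S2 trains have the same period and,
     after the Shannon transform's dynamic-range compression, very
     similar heights, and the S2 train's intervals are — counter to first
     intuition — slightly *more* regular (an S2 onset averages the jitter
     of two neighboring cycle lengths). Regularity therefore cannot
     disambiguate them. Physiology can: systole is the shorter fraction
     of the cycle at rest. If the interior envelope maxima between train
     peaks sit in the latter half of the gaps, the train is relabeled S2
     and the complementary train is chained instead; near-ties go to the
     taller train as S1.
   * *Peak time by centroid.* `-x² ln x²` is non-monotonic in |x| with a
     maximum at `|x| = e^{-1/2} ≈ 0.61`, so the top of a full-scale S1
     lobe can flatten or split into two shoulders. The argmax is then
     biased to one shoulder; the energy centroid of the half-height lobe
     is used as the peak time instead.
5. **S2 search** (`detect_s2_peaks`) — the highest interior envelope
   maximum strictly between adjacent S1 peaks, excluding a margin of 15%
   of the gap (at least one frame) around each S1 lobe. Cycles with no
   interior maximum yield an explicit missing-S2 placeholder: they are
   excluded from the cycle list but always reported, never silently
   dropped.
6. **S2 outlier rejection** (`filter_s2_outliers`) — a candidate is
   rejected when its envelope height or its S1→S2 lag deviates from the
   median by more than `s2_outlier_k` (default 3) robust standard
   deviations (MAD × 1.4826). The robust sigma is floored at the
   measurement resolution — 10 ms (one envelope hop) for lags, 2% of the
   typical height — because in clean recordings the MAD collapses toward
   zero and would otherwise flag deviations far below what the envelope
   can resolve. Fewer than 3 candidates: the rule cannot be estimated,
   so candidates pass through with a warning.
7. **Boundaries** (`locate_boundaries`) — scanning outward from a peak,
   the boundary is the first event met on each side: the interpolated
   crossing of `boundary_fraction` (default 0.1) of the peak height, or a
   *significant* local valley. "Significant" means at or below half the
   peak height: the split top of a Shannon lobe (see above) creates a
   shallow valley between shoulders that must not terminate the burst.
   Edge-clipped boundaries are flagged.
8. **Trimming** (`trim_partial_cycles`) — audio and labels are cropped so
   the output starts at the first S1 onset (time 0) and ends at the last
   complete cycle. Cropping happens on the sample grid and all labels
   shift by one constant, so interval durations are preserved to within
   floating-point rounding (≤ 1 ulp; the audio/label alignment error is
   at most half a sample).
9. **Heart rate** — `round(60 / median cycle duration)`, half away from
   zero, reported as an integer like reference devices print. The median
   is robust to a single missed or spurious cycle.

Every parameter lives in `segmenter_params()` and is logged by the CLI
and in the pipeline manifest.

## The feature battery

Statistics use *population* conventions (n denominators) and non-excess
kurtosis (Gaussian baseline 3); for zero-mean segments this makes
`STD == RMS` an identity, which the tests assert. Frame-level amplitude
features use 0.02 s frames / 0.01 s hop; per-frame level is
`20 log10(frame RMS)` dBFS, floored at −120 dB for silent frames, and
segments shorter than one frame are measured whole and flagged.

Fundamental frequency is tracked per 0.04 s frame (0.01 s hop) by
normalized cross-correlation over lags corresponding to 50–400 Hz, with
parabolic lag interpolation. The normalization divides by the energies of
both the leading and trailing sub-windows, so a clean periodic frame
scores ~1 regardless of window taper. Among correlation local maxima, the
smallest lag within 1% of the global maximum wins — integer multiples of
the true period tie with it numerically and must not cause octave drops.
Frames below a 0.3 voicing threshold are unvoiced. The 50 Hz floor skips
the DC/cycle-rate region; the 400 Hz cap bounds the search to the
physiological range of heart-sound fundamentals.

Jitter is the mean absolute difference of consecutive voiced-frame
periods relative to the mean period (percent). HNR is
`10 log10(r/(1−r))` with `r` the mean correlation peak over voiced
frames; when nothing is voiced, `r` is averaged over all frames so an
aperiodic segment reports a negative HNR rather than nothing. The
harmonic-ratio block summarizes the per-frame correlation peak (a
periodicity score in [0, 1]) over all frames.

`slope_start2max` / `slope_max2end` have no universally fixed definition;
here they are the f0 rise rate from the first voiced frame to the f0
maximum and the fall rate from the maximum to the last voiced frame,
normalized by the mean f0 (units 1/s), and NA when the maximum sits at
the segment edge. All undefined quantities — moments of zero-variance
segments, f0 fields of unvoiced segments, jitter with fewer than two
voiced frames — are reported as `NA`, never as 0: a structural zero and
a missing value must remain distinguishable downstream.

## The synthetic generator

`generate_pcg()` emulates the features the segmenter relies on:
quasi-periodic Gaussian-windowed tone bursts (S1 at each cycle onset, S2
at a configurable systolic fraction), cycle-length jitter, and additive
white noise at a configurable SNR. Defaults describe a healthy resting
adult: 72 bpm, S1 0.12 s at 80 Hz, S2 0.10 s at 110 Hz, S2 onset at 35%
of the cycle, S1:S2 amplitude ratio 1.3, 1% cycle jitter, 4 kHz sampling.
The Gaussian window uses sigma = duration/4 with support truncated at
±2 sigma, so the labelled burst support still carries ~13.5% of the peak
amplitude at its edges: real valve-closure transients start abruptly, and
a wider sigma would pad the nominal duration with inaudible tails, making
ground-truth onsets physically meaningless. The S1 that closes the final
cycle belongs to the next, uncounted cycle, but its audible part is
rendered so the last diastole has a detectable closing boundary.

What the generator does **not** emulate — and hence what passing tests do
not establish about real recordings: murmurs as confounders (available
only via the explicit `add_murmur()` injector), S3/S4, respiratory
amplitude modulation, sensor and contact artifacts, burst-morphology
variability (split S2, varying spectra), and non-stationary heart rates.
Results on synthetic data bound the algorithmic error of the chain, not
its clinical performance.

## Numerical conventions and degenerate inputs

* Time is seconds (double); intervals are half-open `[start, end)`;
  sample `i` (1-based) covers `[(i−1)/fs, i/fs)`. This makes the state
  partition exact.
* Label tracks print 6 decimals (microsecond grid); writing and reading
  a segmentation whose times sit on that grid is bit-exact.
* The segmentation container validates the forced state equalities to a
  tolerance (default 1 µs for parsed files) and then snaps them exact.
  Consecutive cycles must be contiguous; a forward gap is allowed only
  where an intervening cycle was dropped for a missing S2, and overlap
  is always an error.
* Degenerate inputs raise classed errors (`hs_silent_input`,
  `hs_no_peaks`, `hs_insufficient_cycles`, `hs_zero_length_stream`, …)
  so callers and the CLI can distinguish failure modes; the CLI maps
  no-peaks/degenerate segmentation to exit code 2.
* Determinism: the segmenter is purely deterministic; the generator's
  randomness is fully controlled by one seed and restores the caller's
  RNG state.

## Problem sizes used in the checks

The bundled verification runs use twenty 60-second simulated recordings
across 60–100 bpm and 10–20 dB SNR for ground-truth recovery (about
1,600 cycles), 25 random short vectors for the feature-formula oracle,
1,000 random segmentations for label round trips, and the 12-subject
cross-validation table for the paired heart-rate comparison. These sizes
keep the full suite in the low minutes on one CPU while leaving the
statistics stable.

## Known limitations

* Recordings with fewer than two complete cycles cannot be segmented.
* Sustained loud murmurs can disturb the interior-maximum S2 search; the
  outlier filter rejects affected cycles rather than relabeling them.
* Tachycardia near the 200 bpm band edge shortens systole toward the
  candidate-merge window; the 40–200 bpm band is a parameter, but the
  defaults target resting adult recordings.
* MP3 ingestion requires an external decoder and is not available in
  this build; the canonical format is 16-bit PCM WAV.
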