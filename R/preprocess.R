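# Amplitude standardization, band-limiting, Shannon-energy envelope and
# edge trimming. These are the conditioning steps feeding peak detection;
# feature extraction runs on the standardized (not band-passed) audio.

#' Standardize a recording (DC removal + peak normalization)
#'
#' Subtracts the mean, then rescales so `max(abs(samples)) == 1`. This is
#' the "amplification" step that makes small stethoscope signals fill the
#' display range while keeping dB features interpretable as dBFS.
#'
#' @param recording an [audio_recording()].
#' @return standardized [audio_recording()].
#' @export
standardize <- function(recording) {
  stopifnot(inherits(recording, "audio_recording"))
  x <- recording$samples - mean(recording$samples)
  peak <- max(abs(x))
  if (peak == 0)
    hs_error("hs_silent_input", "cannot standardize an all-zero (silent) recording")
  audio_recording(x / peak, recording$sample_rate, recording$source_path)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward
#' ([signal::filtfilt()]), i.e. zero phase shift and an effective 4th-order
#' magnitude response from a 2nd-order design. Length and sample rate are
#' preserved.
#'
#' @param recording an [audio_recording()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @return filtered [audio_recording()].
#' @export
bandpass <- function(recording, low_hz = 25, high_hz = 400) {
  stopifnot(inherits(recording, "audio_recording"))
  fs <- recording$sample_rate
  if (!is.finite(low_hz) || !is.finite(high_hz) ||
      low_hz <= 0 || low_hz >= high_hz || high_hz >= fs / 2)
    hs_error("hs_invalid_band", sprintf(
      "band edges must satisfy 0 < low (%.3g) < high (%.3g) < fs/2 (%.3g)",
      low_hz, high_hz, fs / 2))
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, recording$samples)
  audio_recording(y, fs, recording$source_path)
}

#' Envelope container
#'
#' Smoothed nonnegative energy curve on which heart-sound peaks are
#' detected. Value `i` is the average Shannon energy of the analysis frame
#' centered at `t0_s + (i-1) * frame_hop_s`.
#'
#' @param values nonnegative numeric vector.
#' @param frame_hop_s hop between frame centers, seconds.
#' @param frame_len_s analysis frame length, seconds (>= hop).
#' @param t0_s time of the first frame center, seconds.
#' @return object of class `pcg_envelope`.
#' @export
pcg_envelope <- function(values, frame_hop_s, frame_len_s, t0_s) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    hs_error("hs_invalid_envelope", "envelope values must be finite and nonnegative")
  if (!is.finite(frame_hop_s) || frame_hop_s <= 0 || frame_len_s < frame_hop_s)
    hs_error("hs_invalid_envelope", "need frame_hop_s > 0 and frame_len_s >= frame_hop_s")
  structure(list(values = values, frame_hop_s = frame_hop_s,
                 frame_len_s = frame_len_s, t0_s = t0_s),
            class = "pcg_envelope")
}

#' Frame-center times of an envelope
#' @param envelope a `pcg_envelope`.
#' @return numeric vector of times in seconds.
#' @export
envelope_times <- function(envelope) {
  envelope$t0_s + (seq_along(envelope$values) - 1L) * envelope$frame_hop_s
}

#' Normalized average Shannon-energy envelope
#'
#' Per-sample Shannon energy `-x^2 * log(x^2)` (defined as 0 at `x = 0` by
#' continuity) averaged over sliding frames. Peak detection uses thresholds
#' relative to the envelope maximum, so no further normalization is applied
#' and closed-form envelope values are preserved. The Shannon transform boosts medium-level components relative to both
#' low-level noise and the strongest transients, which is what makes it the
#' standard detection envelope for phonocardiograms.
#'
#' @param recording a standardized [audio_recording()] (`|x| <= 1`).
#' @param frame_len_s analysis frame length in seconds (default 0.02).
#' @param frame_hop_s hop between frames in seconds (default 0.01).
#' @return a [pcg_envelope()].
#' @export
shannon_envelope <- function(recording, frame_len_s = 0.02, frame_hop_s = 0.01) {
  stopifnot(inherits(recording, "audio_recording"))
  fs <- recording$sample_rate
  x <- recording$samples
  flen <- max(1L, round(frame_len_s * fs))
  fhop <- max(1L, round(frame_hop_s * fs))
  if (flen > length(x))
    hs_error("hs_frame_too_long", sprintf(
      "frame of %d samples exceeds signal length %d", flen, length(x)))
  x2 <- x * x
  se <- ifelse(x2 > 0, -x2 * log(x2), 0)
  starts <- seq.int(1L, length(x) - flen + 1L, by = fhop)
  # mean over each frame via cumulative sum
  cs <- c(0, cumsum(se))
  vals <- (cs[starts + flen] - cs[starts]) / flen
  vals[vals < 0] <- 0   # guard tiny negative round-off
  pcg_envelope(vals,
               frame_hop_s = fhop / fs,
               frame_len_s = flen / fs,
               t0_s = (flen / 2) / fs)
}

#' Trim partial cycles at the file edges
#'
#' Crops audio and labels so the output starts at the first detected S1
#' onset (shifted to time 0) and ends at the last complete cycle's end.
#' Cropping happens on the sample grid (nearest sample to the first S1
#' onset), and every label is shifted by exactly that many samples, so all
#' retained interval durations are preserved exactly.
#'
#' @param recording the [audio_recording()] the segmentation was derived from.
#' @param segmentation a [cycle_segmentation()] with at least 2 complete cycles.
#' @return list with elements `recording` and `segmentation`, both cropped.
#' @export
trim_partial_cycles <- function(recording, segmentation) {
  stopifnot(inherits(recording, "audio_recording"),
            inherits(segmentation, "cycle_segmentation"))
  if (n_cycles(segmentation) < 2L)
    hs_error("hs_insufficient_cycles",
             "need at least 2 complete cycles to trim; got fewer")
  fs <- recording$sample_rate
  t_first <- min(segmentation$start_s)
  t_last <- max(segmentation$end_s)
  i0 <- max(0L, as.integer(round(t_first * fs)))
  i1 <- min(length(recording$samples), as.integer(round(t_last * fs)))
  if (i1 <= i0) i1 <- min(length(recording$samples), i0 + 1L)
  rec <- audio_recording(recording$samples[(i0 + 1L):i1], fs,
                         recording$source_path)
  shift <- t_first           # labels shift so the first S1 starts at 0
  df <- as.data.frame(segmentation)
  df$start_s <- df$start_s - shift
  df$end_s <- df$end_s - shift
  list(recording = rec, segmentation = cycle_segmentation(df))
}
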