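# Parametric synthetic phonocardiogram generator with exact ground-truth
# labels. S1 and S2 are Gaussian-windowed tone bursts placed on a
# quasi-periodic cycle grid; defaults emulate a healthy resting adult
# (HR 72, S1 longer and stronger than S2, systole ~35% of the cycle).

#' Configuration for the synthetic PCG generator
#'
#' @param heart_rate_bpm heart rate in beats/min, within \[40, 200\]
#'   (default 72, a healthy resting adult).
#' @param duration_s total length in seconds (default 60, matching a
#'   typical 1-minute auscultation recording); must exceed 2 cycles.
#' @param s1_duration_s,s2_duration_s burst durations in seconds (defaults
#'   0.12 and 0.10, so S1 is longer than S2 as physiology dictates).
#' @param s1_freq_hz,s2_freq_hz tone-burst center frequencies in Hz
#'   (defaults 80 and 110; S2 is higher-pitched than S1).
#' @param s2_onset_fraction fraction of the cycle at which S2 (diastole)
#'   starts (default 0.35).
#' @param s1_s2_amplitude_ratio S1:S2 peak amplitude ratio (> 0, default 1.3).
#' @param cycle_jitter_pct standard deviation of cycle-length noise as a
#'   percentage of the nominal cycle (default 1).
#' @param snr_db additive white-noise level: signal-to-noise ratio in dB
#'   relative to the signal RMS (default `Inf` = no noise).
#' @param sample_rate_hz sampling rate in Hz (default 4000).
#' @param seed integer seed controlling all randomness (default 1).
#' @return object of class `synthetic_pcg_config`.
#' @export
synthetic_pcg_config <- function(heart_rate_bpm = 72, duration_s = 60,
                                 s1_duration_s = 0.12, s2_duration_s = 0.10,
                                 s1_freq_hz = 80, s2_freq_hz = 110,
                                 s2_onset_fraction = 0.35,
                                 s1_s2_amplitude_ratio = 1.3,
                                 cycle_jitter_pct = 1,
                                 snr_db = Inf,
                                 sample_rate_hz = 4000,
                                 seed = 1L) {
  cfg <- list(heart_rate_bpm = heart_rate_bpm, duration_s = duration_s,
              s1_duration_s = s1_duration_s, s2_duration_s = s2_duration_s,
              s1_freq_hz = s1_freq_hz, s2_freq_hz = s2_freq_hz,
              s2_onset_fraction = s2_onset_fraction,
              s1_s2_amplitude_ratio = s1_s2_amplitude_ratio,
              cycle_jitter_pct = cycle_jitter_pct, snr_db = snr_db,
              sample_rate_hz = sample_rate_hz, seed = as.integer(seed))
  cycle <- 60 / heart_rate_bpm
  bad <-
    !is.finite(heart_rate_bpm) || heart_rate_bpm < 40 || heart_rate_bpm > 200 ||
    !is.finite(duration_s) || duration_s <= 2 * cycle ||
    s1_duration_s <= 0 || s2_duration_s <= 0 ||
    s1_duration_s + s2_duration_s >= cycle ||
    s2_onset_fraction <= 0 || s2_onset_fraction >= 1 ||
    s1_s2_amplitude_ratio <= 0 || cycle_jitter_pct < 0 ||
    sample_rate_hz <= 0 || is.na(cfg$seed)
  # S2 must start after S1 ends and end before the cycle does
  bad <- bad || s2_onset_fraction * cycle <= s1_duration_s ||
    s2_onset_fraction * cycle + s2_duration_s >= cycle
  if (bad)
    hs_error("hs_invalid_config", "invalid synthetic PCG configuration")
  structure(cfg, class = "synthetic_pcg_config")
}

# Gaussian-windowed sinusoid burst. sigma = duration/4 (support truncated
# at +/- 2 sigma), so the labelled support edges still carry ~13.5% of the
# peak amplitude: the nominal duration is acoustically meaningful, like a
# real valve-closure transient that starts abruptly.
.tone_burst <- function(t, onset, duration, freq, amp) {
  center <- onset + duration / 2
  sigma <- duration / 4
  inside <- t >= onset & t < onset + duration
  out <- numeric(length(t))
  ti <- t[inside]
  out[inside] <- amp * exp(-(ti - center)^2 / (2 * sigma^2)) *
    sin(2 * pi * freq * (ti - onset))
  out
}

#' Generate a synthetic phonocardiogram with ground-truth labels
#'
#' The signal is a sum over cardiac cycles of Gaussian-windowed sinusoid
#' bursts: S1 at each cycle start, S2 at `s2_onset_fraction` of the cycle.
#' Cycle lengths are `60/heart_rate_bpm` perturbed by Gaussian noise of sd
#' `cycle_jitter_pct` percent; white noise is added at `snr_db`. Identical
#' seeds give bit-identical output. Ground-truth labels mark the burst
#' supports and the derived systole/diastole states.
#'
#' @param config a [synthetic_pcg_config()].
#' @return list with elements `recording` (an [audio_recording()]), `truth`
#'   (a [cycle_segmentation()]) and `config`.
#' @export
generate_pcg <- function(config = synthetic_pcg_config()) {
  stopifnot(inherits(config, "synthetic_pcg_config"))
  fs <- config$sample_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  nominal <- 60 / config$heart_rate_bpm

  # RNG isolated from (and deterministic regardless of) the caller's stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  # cycle onsets: keep cycles whose full span fits in the recording
  onsets <- 0; lens <- numeric()
  repeat {
    len <- nominal * (1 + (config$cycle_jitter_pct / 100) * stats::rnorm(1))
    # jitter may never squeeze a cycle below what its two bursts need
    len <- max(len,
               (config$s2_duration_s + 0.01) / (1 - config$s2_onset_fraction),
               (config$s1_duration_s + 0.005) / config$s2_onset_fraction)
    if (onsets[length(onsets)] + len > config$duration_s + 1e-9) break
    lens <- c(lens, len)
    onsets <- c(onsets, onsets[length(onsets)] + len)
  }
  n_cyc <- length(lens)
  if (n_cyc < 2L)
    hs_error("hs_invalid_config", "duration too short for 2 complete cycles")

  x <- numeric(n)
  rows <- vector("list", n_cyc)
  for (k in seq_len(n_cyc)) {
    a <- onsets[k]; len <- lens[k]
    s2_on <- a + config$s2_onset_fraction * len
    x <- x + .tone_burst(t, a, config$s1_duration_s, config$s1_freq_hz, 1)
    x <- x + .tone_burst(t, s2_on, config$s2_duration_s, config$s2_freq_hz,
                         1 / config$s1_s2_amplitude_ratio)
    rows[[k]] <- data.frame(
      cycle = k, state = .hs_states,
      start_s = c(a, a, s2_on, s2_on),
      end_s = c(a + config$s1_duration_s, s2_on,
                s2_on + config$s2_duration_s, a + len),
      stringsAsFactors = FALSE)
  }
  # the S1 that closes the final cycle belongs to the next (uncounted)
  # cycle; render whatever part of it falls inside the recording so the
  # final diastole has its audible closing boundary
  x <- x + .tone_burst(t, onsets[n_cyc + 1L], config$s1_duration_s,
                       config$s1_freq_hz, 1)
  if (is.finite(config$snr_db)) {
    rms <- sqrt(mean(x^2))
    x <- x + stats::rnorm(n, sd = rms * 10^(-config$snr_db / 20))
  }
  list(recording = audio_recording(x, fs, source_path = "synthetic"),
       truth = cycle_segmentation(do.call(rbind, rows)),
       config = config)
}

#' Add a band-limited murmur to one phase of a synthetic PCG
#'
#' Band-limited Gaussian noise is added only inside the chosen phase's
#' intervals (systole or diastole); the ground-truth labels are unchanged.
#'
#' @param recording an [audio_recording()].
#' @param truth the matching [cycle_segmentation()].
#' @param band_hz length-2 numeric, murmur band in Hz.
#' @param rel_level murmur RMS as a fraction of the recording RMS, in
#'   `[0, 1)`; 0 returns the input unchanged.
#' @param phase `"SYSTOLE"` or `"DIASTOLE"`.
#' @param seed integer seed for the murmur noise.
#' @return the modified [audio_recording()].
#' @export
add_murmur <- function(recording, truth, band_hz = c(150, 400),
                       rel_level = 0.2, phase = "SYSTOLE", seed = 1L) {
  stopifnot(inherits(recording, "audio_recording"),
            inherits(truth, "cycle_segmentation"))
  if (!phase %in% c("SYSTOLE", "DIASTOLE"))
    hs_error("hs_unknown_phase",
             sprintf("unknown phase '%s' (use SYSTOLE or DIASTOLE)", phase))
  if (!is.finite(rel_level) || rel_level < 0 || rel_level >= 1)
    hs_error("hs_invalid_config", "rel_level must lie in [0, 1)")
  if (rel_level == 0) return(recording)
  fs <- recording$sample_rate
  n <- length(recording$samples)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  noise <- stats::rnorm(n)
  bf <- signal::butter(2, band_hz / (fs / 2), type = "pass")
  noise <- signal::filtfilt(bf, noise)
  noise <- noise / sqrt(mean(noise^2)) * rel_level * sqrt(mean(recording$samples^2))

  mask <- logical(n)
  ph <- truth[truth$state == phase, , drop = FALSE]
  tvec <- (seq_len(n) - 1L) / fs
  for (i in seq_len(nrow(ph)))
    mask <- mask | (tvec >= ph$start_s[i] & tvec < ph$end_s[i])
  x <- recording$samples
  x[mask] <- x[mask] + noise[mask]
  audio_recording(x, fs, recording$source_path)
}
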