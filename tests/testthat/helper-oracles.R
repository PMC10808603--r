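# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain loops, deliberately not reusing any package internals, so they
# can arbitrate the vectorized implementations.

make_sine <- function(freq_hz, dur_s, fs = 8000, amp = 1) {
  t <- (seq_len(round(dur_s * fs)) - 1) / fs
  audio_recording(amp * sin(2 * pi * freq_hz * t), fs)
}

whole_interval <- function(recording, state = "S1") {
  segment_interval(0, length(recording$samples) / recording$sample_rate, state)
}

# brute-force shape statistics: explicit loops, population conventions
oracle_stats <- function(x) {
  n <- length(x)
  m <- 0; for (v in x) m <- m + v; m <- m / n
  absomean <- 0; for (v in x) absomean <- absomean + abs(v)
  absomean <- absomean / n
  m2 <- 0; m3 <- 0; m4 <- 0; ss <- 0; rootsum <- 0
  for (v in x) {
    d <- v - m
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
    ss <- ss + v^2; rootsum <- rootsum + sqrt(abs(v))
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  rms <- sqrt(ss / n)
  peak <- max(abs(x))
  list(absomean = absomean,
       STD = sqrt(m2),
       skew = if (m2 > 0) m3 / m2^1.5 else NA_real_,
       kurt = if (m2 > 0) m4 / m2^2 else NA_real_,
       max = max(x), min = min(x), peak2valley = max(x) - min(x),
       RMS = rms,
       shapefactor = rms / absomean,
       impulsefactor = peak / absomean,
       marginfactor = peak / (rootsum / n)^2,
       energy = ss)
}

# brute-force per-frame dB levels (frame RMS in a loop)
oracle_amplitude <- function(x, fs, frame_len_s = 0.02, frame_hop_s = 0.01,
                             floor_db = -120) {
  flen <- max(1, round(frame_len_s * fs))
  fhop <- max(1, round(frame_hop_s * fs))
  if (length(x) < flen) {
    levels <- 20 * log10(sqrt(mean(x^2)))
  } else {
    levels <- c()
    s <- 1
    while (s + flen - 1 <= length(x)) {
      fr <- x[s:(s + flen - 1)]
      ss <- 0; for (v in fr) ss <- ss + v^2
      r <- sqrt(ss / flen)
      levels <- c(levels, if (r > 10^(floor_db / 20)) 20 * log10(r) else floor_db)
      s <- s + fhop
    }
  }
  levels[!is.finite(levels)] <- floor_db
  list(maxdb = max(levels), mindb = min(levels),
       meandb = mean(levels), middledb = median(levels))
}

# random valid cycle segmentation on the integer-microsecond grid: label
# tracks print 6 decimals, and k/1e6 is the correctly-rounded double of the
# printed decimal, so round trips are bit-exact
random_segmentation <- function(n_cycles = 5L) {
  us <- function(lo, hi) round(runif(1, lo * 1e6, hi * 1e6))  # integer us
  rows <- list(); onset <- us(0, 0.5)
  for (k in seq_len(n_cycles)) {
    cyc <- us(0.4, 1.4)
    s1d <- us(0.05, 0.18)
    sys <- s1d + us(0.02, max(0.021, 0.6 * cyc / 1e6 - s1d / 1e6))
    s2d <- us(0.04, max(0.041, min(0.15, (cyc - sys) / 1e6 - 0.01)))
    s1s <- onset; s2s <- onset + sys; nxt <- onset + cyc
    # canonicalize each time to the double its 6-decimal printout parses
    # back to (near-midpoint decimals can differ by one ulp otherwise)
    t6 <- function(us) as.numeric(sprintf("%.6f", us / 1e6))
    rows[[k]] <- data.frame(
      cycle = k, state = c("S1", "SYSTOLE", "S2", "DIASTOLE"),
      start_s = t6(c(s1s, s1s, s2s, s2s)),
      end_s = t6(c(s1s + s1d, s2s, min(s2s + s2d, nxt - 1), nxt)))
    onset <- nxt
  }
  cycle_segmentation(do.call(rbind, rows))
}

# minimal stereo 16-bit PCM WAV writer for mixdown tests
write_stereo_wav <- function(left, right, fs, path) {
  inter <- as.integer(round(pmin(1, pmax(-1, c(rbind(left, right)))) * 32767))
  n_bytes <- length(inter) * 2L
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")           # stereo
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(inter, con, size = 2L, endian = "little")
  invisible(path)
}
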