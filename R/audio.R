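#' Audio recording container
#'
#' Bundles a mono sample vector with its sample rate. Samples are
#' dimensionless full-scale amplitudes in \[-1, 1\] (integer PCM is rescaled
#' on read; no gain is applied beyond that). Time convention throughout the
#' package: sample `i` (1-based) covers the half-open interval
#' \[(i-1)/fs, i/fs) seconds.
#'
#' @param samples numeric vector of finite amplitudes, length >= 1.
#' @param sample_rate sampling rate in Hz, a positive integer.
#' @param source_path optional provenance string (file of origin).
#' @return An object of class `audio_recording` with elements `samples`,
#'   `sample_rate` and `source_path`.
#' @export
audio_recording <- function(samples, sample_rate, source_path = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    hs_error("hs_zero_length_stream", "recording must contain at least one sample")
  if (!all(is.finite(samples)))
    hs_error("hs_invalid_audio", "recording contains non-finite samples")
  sample_rate <- as.integer(sample_rate)
  if (length(sample_rate) != 1L || is.na(sample_rate) || sample_rate <= 0L)
    hs_error("hs_invalid_audio", "sample_rate must be a positive integer")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         source_path = source_path),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<audio_recording> %d samples @ %d Hz (%.3f s)",
              length(x$samples), x$sample_rate, dur))
  if (!is.null(x$source_path)) cat(" [", x$source_path, "]", sep = "")
  cat("\n  peak |amplitude| =", format(max(abs(x$samples)), digits = 4), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `audio_recording`.
#' @return length in seconds (numeric scalar).
#' @export
duration_s <- function(recording) {
  length(recording$samples) / recording$sample_rate
}

#' Read an audio file as a mono recording
#'
#' Reads WAV PCM audio (8/16/32-bit integer or 32/64-bit IEEE float).
#' Multi-channel input is mixed down to mono by averaging channels. Integer
#' PCM is rescaled to full-scale \[-1, 1\]; no other gain change is applied
#' and the sample rate is preserved. MP3 is recognized by extension but this
#' build carries no decoder, so `.mp3` input raises the unsupported-codec
#' error.
#'
#' @param path path to the audio file.
#' @return An [audio_recording()].
#' @export
read_audio <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    hs_error("hs_missing_file", "path must be a single file path")
  if (!file.exists(path))
    hs_error("hs_missing_file", sprintf("audio file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mp3")
    hs_error("hs_unsupported_codec",
             "MP3 input requires an external decoder, which is not available; convert to WAV PCM")
  read_wav(path)
}

# --- WAV PCM (RIFF) ---------------------------------------------------------
# Hand-rolled RIFF walker: chunks are id(4) size(4, little-endian) payload,
# padded to even length. Only fmt/data chunks are interpreted.

read_wav <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 12L ||
      rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE") {
    if (length(raw) == 0L)
      hs_error("hs_zero_length_stream", sprintf("empty audio file: %s", path))
    hs_error("hs_unsupported_codec",
             sprintf("not a RIFF/WAVE file: %s", path))
  }
  pos <- 13L
  fmt <- NULL
  data_raw <- NULL
  n_raw <- length(raw)
  while (pos + 8L <= n_raw + 1L) {
    id <- rawToChar(raw[pos:(pos + 3L)])
    size <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                    endian = "little")
    body_start <- pos + 8L
    body_end <- min(body_start + size - 1L, n_raw)
    if (id == "fmt ") {
      body <- raw[body_start:body_end]
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", size = 2L,
                               endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", size = 2L,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(body[5:8], "integer", size = 4L,
                              endian = "little"),
        bits = readBin(body[15:16], "integer", size = 2L,
                       endian = "little", signed = FALSE)
      )
    } else if (id == "data") {
      data_raw <- if (size > 0L && body_end >= body_start)
        raw[body_start:body_end] else raw(0L)
    }
    pos <- body_start + size + (size %% 2L)
  }
  if (is.null(fmt))
    hs_error("hs_unsupported_codec", sprintf("WAV file has no fmt chunk: %s", path))
  if (is.null(data_raw) || length(data_raw) == 0L)
    hs_error("hs_zero_length_stream",
             sprintf("WAV file has no audio samples: %s", path))

  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) is not unpacked; plain PCM (1) and
  # IEEE float (3) cover everything this package writes or expects.
  x <- switch(
    as.character(fmt$audio_format),
    "1" = switch(
      as.character(fmt$bits),
      "8"  = (as.numeric(readBin(data_raw, "integer", n = length(data_raw),
                                 size = 1L, signed = FALSE)) - 128) / 128,
      "16" = as.numeric(readBin(data_raw, "integer",
                                n = length(data_raw) %/% 2L,
                                size = 2L, endian = "little")) / 32768,
      "32" = as.numeric(readBin(data_raw, "integer",
                                n = length(data_raw) %/% 4L,
                                size = 4L, endian = "little")) / 2147483648,
      hs_error("hs_unsupported_codec",
               sprintf("unsupported PCM bit depth: %d", fmt$bits))
    ),
    "3" = switch(
      as.character(fmt$bits),
      "32" = readBin(data_raw, "numeric", n = length(data_raw) %/% 4L,
                     size = 4L, endian = "little"),
      "64" = readBin(data_raw, "numeric", n = length(data_raw) %/% 8L,
                     size = 8L, endian = "little"),
      hs_error("hs_unsupported_codec",
               sprintf("unsupported float bit depth: %d", fmt$bits))
    ),
    hs_error("hs_unsupported_codec",
             sprintf("unsupported WAV audio format code: %d", fmt$audio_format))
  )
  if (length(x) == 0L)
    hs_error("hs_zero_length_stream", sprintf("zero-length audio stream: %s", path))
  nch <- max(1L, fmt$channels)
  if (nch > 1L) {
    usable <- (length(x) %/% nch) * nch
    x <- rowMeans(matrix(x[seq_len(usable)], ncol = nch, byrow = TRUE))
  }
  audio_recording(x, fmt$sample_rate, source_path = path)
}

#' Write a recording to a 16-bit PCM WAV file
#'
#' Samples outside \[-1, 1\] are clipped. This is the package's canonical
#' on-disk audio format.
#'
#' @param recording an [audio_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path) {
  stopifnot(inherits(recording, "audio_recording"))
  x <- pmin(1, pmax(-1, recording$samples))
  pcm <- as.integer(round(x * 32767))
  fs <- recording$sample_rate
  n_bytes <- length(pcm) * 2L

  con <- tryCatch(file(path, "wb"), condition = function(e)
    hs_error("hs_unwritable_path", sprintf("cannot open for writing: %s", path)))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
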