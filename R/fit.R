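#' Segment a phonocardiogram into four-state cardiac-cycle labels
#'
#' The central fitting function: composes standardization, band-pass
#' filtering, Shannon-envelope computation, S1/S2 peak detection, outlier
#' rejection, boundary localization, cycle-label assembly and (optionally)
#' edge trimming, and returns a classed result with `print`, `summary` and
#' `plot` methods.
#'
#' Detection runs on the band-passed signal; the returned recording and all
#' downstream features use the standardized but unfiltered audio, so dB
#' features stay interpretable as dBFS of the original waveform.
#'
#' @param x an [audio_recording()] or a path readable by [read_audio()].
#' @param params a [segmenter_params()].
#' @param band_hz length-2 numeric, detection band-pass edges in Hz
#'   (default `c(25, 400)`, covering S1/S2 energy).
#' @param trim if TRUE (default), crop audio and labels to whole cycles via
#'   [trim_partial_cycles()] so the first S1 starts at time 0.
#' @param frame_len_s,frame_hop_s envelope frame length and hop in seconds.
#' @return An object of class `pcg_segmentation`: a list with elements
#'   `segmentation` (a [cycle_segmentation()]), `recording` (standardized,
#'   trimmed), `envelope`, `s1_peaks`, `s2_peaks`, `removed_s2_cycles`,
#'   `missing_s2_cycles`, `hr_bpm`, `validation`, `params`, `band_hz`.
#' @export
segment_pcg <- function(x, params = segmenter_params(),
                        band_hz = c(25, 400), trim = TRUE,
                        frame_len_s = 0.02, frame_hop_s = 0.01) {
  rec <- if (inherits(x, "audio_recording")) x else read_audio(x)
  stopifnot(inherits(params, "segmenter_params"))

  rec_std <- tryCatch(standardize(rec), hs_silent_input = function(e)
    hs_error(c("hs_no_peaks", "hs_silent_input"),
             "silent recording: no heart-sound peaks can be detected"))
  rec_filt <- standardize(bandpass(rec_std, band_hz[1], band_hz[2]))
  env <- shannon_envelope(rec_filt, frame_len_s, frame_hop_s)

  s1 <- detect_s1_peaks(env, params)
  if (nrow(s1) < 2L)
    hs_error("hs_insufficient_cycles",
             "fewer than 2 S1 peaks detected; cannot form a cycle")
  s2 <- detect_s2_peaks(env, s1, params)
  s2f <- withCallingHandlers(
    filter_s2_outliers(s2, params),
    hs_too_few_s2 = function(w) invokeRestart("muffleWarning"))
  removed <- attr(s2f, "removed_cycles") %||% integer()

  s1_iv <- lapply(seq_len(nrow(s1)), function(i)
    locate_boundaries(env, s1[i, ], params))
  ok <- which(!s2f$missing)
  s2_iv <- lapply(ok, function(i) locate_boundaries(env, s2f[i, ], params))
  seg <- build_cycle_labels(s1_iv, s2_iv)
  missing <- attr(seg, "missing_s2") %||% integer()

  rec_out <- rec_std
  if (isTRUE(trim) && n_cycles(seg) >= 2L) {
    shift <- min(seg$start_s)
    tr <- trim_partial_cycles(rec_std, seg)
    rec_out <- tr$recording
    miss_keep <- attr(seg, "missing_s2")
    seg <- tr$segmentation
    attr(seg, "missing_s2") <- miss_keep
    # keep envelope and peak times in the trimmed time frame
    env$t0_s <- env$t0_s - shift
    s1$time_s <- s1$time_s - shift
    s2f$time_s <- s2f$time_s - shift
  }

  hr <- if (n_cycles(seg) >= 2L) estimate_heart_rate(seg) else NA_integer_
  val <- validate_physiology(seg, params = params)

  structure(list(
    segmentation = seg, recording = rec_out, envelope = env,
    s1_peaks = s1, s2_peaks = s2f,
    removed_s2_cycles = removed, missing_s2_cycles = missing,
    hr_bpm = hr, validation = val,
    params = params, band_hz = band_hz
  ), class = "pcg_segmentation")
}

#' @export
print.pcg_segmentation <- function(x, ...) {
  cat("Phonocardiogram segmentation\n")
  cat(sprintf("  %d complete cardiac cycle(s); estimated heart rate %s bpm\n",
              n_cycles(x$segmentation),
              if (is.na(x$hr_bpm)) "NA" else x$hr_bpm))
  cat(sprintf("  %d S1 peak(s); %d S2 candidate(s) rejected as outliers; %d cycle(s) missing S2\n",
              nrow(x$s1_peaks), length(x$removed_s2_cycles),
              length(x$missing_s2_cycles)))
  cat("  physiology checks:", if (x$validation$all_pass) "pass" else "FAIL", "\n")
  invisible(x)
}

#' @export
summary.pcg_segmentation <- function(object, ...) {
  d <- cycle_durations(object$segmentation)
  tab <- rbind(
    s1 = c(mean(d$s1), stats::sd(d$s1)),
    s2 = c(mean(d$s2), stats::sd(d$s2)),
    systole = c(mean(d$systole), stats::sd(d$systole)),
    diastole = c(mean(d$diastole), stats::sd(d$diastole)),
    cycle = c(mean(d$cycle_duration), stats::sd(d$cycle_duration))
  )
  colnames(tab) <- c("mean_s", "sd_s")
  out <- list(durations = tab, n_cycles = n_cycles(object$segmentation),
              hr_bpm = object$hr_bpm, validation = object$validation,
              params = object$params)
  class(out) <- "summary.pcg_segmentation"
  out
}

#' @export
print.summary.pcg_segmentation <- function(x, ...) {
  cat(sprintf("Segmentation of %d cardiac cycles (HR %s bpm)\n\n",
              x$n_cycles, if (is.na(x$hr_bpm)) "NA" else x$hr_bpm))
  cat("Segment durations (s), mean +/- sd over cycles:\n")
  print(round(x$durations, 4))
  cat("\n")
  print(x$validation)
  invisible(x)
}

#' Plot a segmented phonocardiogram
#'
#' Two stacked panels: the standardized waveform with the four states
#' shaded, and the Shannon envelope with detected S1/S2 peaks.
#'
#' @param x a `pcg_segmentation` from [segment_pcg()].
#' @param xlim optional time window (seconds) to display.
#' @param ... unused.
#' @export
plot.pcg_segmentation <- function(x, xlim = NULL, ...) {
  rec <- x$recording
  tt <- (seq_along(rec$samples) - 1L) / rec$sample_rate
  if (is.null(xlim)) xlim <- range(tt)
  old <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  cols <- c(S1 = grDevices::rgb(0.85, 0.3, 0.3, 0.30),
            SYSTOLE = grDevices::rgb(1, 1, 0.6, 0.25),
            S2 = grDevices::rgb(0.3, 0.3, 0.85, 0.30),
            DIASTOLE = grDevices::rgb(0.6, 0.9, 0.6, 0.25))
  graphics::plot(tt, rec$samples, type = "l", col = "grey25",
                 xlab = "", ylab = "amplitude", xlim = xlim,
                 main = "standardized PCG")
  seg <- x$segmentation
  for (i in seq_len(nrow(seg)))
    graphics::rect(seg$start_s[i], -1.05, seg$end_s[i], 1.05,
                   col = cols[[seg$state[i]]], border = NA)
  graphics::lines(tt, rec$samples, col = "grey25")
  env <- x$envelope
  graphics::plot(envelope_times(env), env$values, type = "l",
                 xlab = "time (s)", ylab = "Shannon energy", xlim = xlim,
                 main = "detection envelope")
  graphics::points(x$s1_peaks$time_s,
                   rep(max(env$values), nrow(x$s1_peaks)),
                   pch = 25, bg = "red3", col = "red3")
  s2ok <- x$s2_peaks[!x$s2_peaks$missing, , drop = FALSE]
  graphics::points(s2ok$time_s, rep(0.95 * max(env$values), nrow(s2ok)),
                   pch = 25, bg = "blue3", col = "blue3")
  invisible(x)
}
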