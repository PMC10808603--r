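# Per-segment feature battery: durations, frame-level dBFS amplitude
# statistics, waveform shape statistics, autocorrelation-based f0 and
# periodicity measures. Undefined quantities (zero-variance moments,
# unvoiced f0 fields) are reported as NA, never as 0, so downstream
# summaries can exclude them explicitly.

.DB_FLOOR <- -120

# sample indices covered by a half-open interval [start, end)
.segment_index <- function(recording, start_s, end_s) {
  fs <- recording$sample_rate
  n <- length(recording$samples)
  if (!is.finite(start_s) || !is.finite(end_s) || start_s >= end_s ||
      start_s < -1e-9 || end_s > n / fs + 1e-9)
    hs_error("hs_bad_interval", sprintf(
      "interval [%.6f, %.6f) is not inside the %.6f s recording",
      start_s, end_s, n / fs))
  i0 <- max(1L, floor(start_s * fs + 1e-9) + 1L)
  i1 <- min(n, ceiling(end_s * fs - 1e-9))
  if (i1 < i0) i1 <- i0
  i0:i1
}

.as_interval <- function(interval) {
  if (inherits(interval, "segment_interval")) return(interval)
  if (is.list(interval) && all(c("start_s", "end_s") %in% names(interval)))
    return(interval)
  hs_error("hs_bad_interval", "interval must be a segment_interval")
}

# population moments; skew/kurt (non-excess) undefined for zero variance
.pop_moments <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0)
    return(list(mean = m, sd = 0, skew = NA_real_, kurt = NA_real_))
  list(mean = m, sd = sqrt(m2),
       skew = mean((x - m)^3) / m2^1.5,
       kurt = mean((x - m)^4) / m2^2)
}

.frame_starts <- function(n, flen, fhop) seq.int(1L, n - flen + 1L, by = fhop)

#' Frame-level dBFS amplitude features of a segment
#'
#' The segment is cut into 0.02 s frames with 0.01 s hop; each frame's
#' level is `20*log10(frame RMS)` dBFS (0 dB = full scale after
#' standardization). `maxdb`/`mindb`/`middledb`/`meandb` are the max, min,
#' median and mean of the per-frame levels. Silent frames are floored at
#' -120 dB. Segments shorter than one frame are measured as a single
#' whole-segment frame and flagged (`attr(res, "single_frame")`).
#'
#' @param recording a standardized [audio_recording()].
#' @param interval a [segment_interval()] inside the recording.
#' @param frame_len_s,frame_hop_s frame length and hop in seconds.
#' @return named list `maxdb`, `mindb`, `meandb`, `middledb` (dBFS).
#' @export
amplitude_features <- function(recording, interval,
                               frame_len_s = 0.02, frame_hop_s = 0.01) {
  iv <- .as_interval(interval)
  x <- recording$samples[.segment_index(recording, iv$start_s, iv$end_s)]
  fs <- recording$sample_rate
  flen <- max(1L, round(frame_len_s * fs))
  fhop <- max(1L, round(frame_hop_s * fs))
  single <- FALSE
  if (length(x) < flen) {
    frames_rms <- sqrt(mean(x^2))
    single <- TRUE
  } else {
    starts <- .frame_starts(length(x), flen, fhop)
    cs <- c(0, cumsum(x^2))
    frames_rms <- sqrt((cs[starts + flen] - cs[starts]) / flen)
  }
  lvl <- ifelse(frames_rms > 10^(.DB_FLOOR / 20), 20 * log10(frames_rms), .DB_FLOOR)
  res <- list(maxdb = max(lvl), mindb = min(lvl),
              meandb = mean(lvl), middledb = stats::median(lvl))
  attr(res, "single_frame") <- single
  res
}

#' Waveform shape statistics of a segment
#'
#' On the raw segment samples `x`: `absomean = mean(|x|)`; `STD` the
#' population standard deviation; `skew`/`kurt` population skewness and
#' non-excess kurtosis (Gaussian baseline 3); `max`/`min` extrema;
#' `peak2valley = max - min`; `RMS = sqrt(mean(x^2))`;
#' `shapefactor = RMS/absomean`; `impulsefactor = max(|x|)/absomean`;
#' `marginfactor = max(|x|) / mean(sqrt(|x|))^2`; `energy = sum(x^2)`.
#' Zero-variance segments report `skew`/`kurt` as NA.
#'
#' @param recording an [audio_recording()].
#' @param interval a [segment_interval()] with at least 2 samples inside.
#' @return named list of the 12 statistics.
#' @export
stat_features <- function(recording, interval) {
  iv <- .as_interval(interval)
  x <- recording$samples[.segment_index(recording, iv$start_s, iv$end_s)]
  if (length(x) < 2L)
    hs_error("hs_interval_too_short", "segment must hold at least 2 samples")
  mom <- .pop_moments(x)
  absomean <- mean(abs(x))
  rms <- sqrt(mean(x^2))
  peak <- max(abs(x))
  list(absomean = absomean, STD = mom$sd, skew = mom$skew, kurt = mom$kurt,
       max = max(x), min = min(x), peak2valley = max(x) - min(x),
       RMS = rms,
       shapefactor = if (absomean > 0) rms / absomean else NA_real_,
       impulsefactor = if (absomean > 0) peak / absomean else NA_real_,
       marginfactor = if (absomean > 0) peak / mean(sqrt(abs(x)))^2 else NA_real_,
       energy = sum(x^2))
}

# Frame-wise fundamental-frequency track by normalized cross-correlation.
# Per frame (mean-removed, rectangular window) the correlation
#   r(l) = sum(x_t x_{t+l}) / sqrt(sum head^2 * sum tail^2)
# is searched over lags for f in [f_min, f_max]; the peak lag is refined by
# parabolic interpolation. Frames with peak correlation below the voicing
# threshold are unvoiced.
.f0_track <- function(x, fs, frame_len_s = 0.04, frame_hop_s = 0.01,
                      f_min = 50, f_max = 400, voicing_threshold = 0.3) {
  flen <- max(2L, round(frame_len_s * fs))
  fhop <- max(1L, round(frame_hop_s * fs))
  if (length(x) < flen)
    hs_error("hs_interval_too_short", sprintf(
      "segment of %d samples is shorter than one %d-sample f0 frame",
      length(x), flen))
  l_min <- max(2L, floor(fs / f_max))
  l_max <- min(ceiling(fs / f_min), flen - 2L)
  if (l_max <= l_min)
    hs_error("hs_interval_too_short", "f0 frame too short for the search band")
  starts <- .frame_starts(length(x), flen, fhop)
  lags <- l_min:l_max
  res <- lapply(starts, function(s) {
    fr <- x[s:(s + flen - 1L)]
    fr <- fr - mean(fr)
    e_all <- sum(fr^2)
    if (e_all <= 0)
      return(c(f0 = NA_real_, r = 0))
    r <- vapply(lags, function(l) {
      head <- fr[1:(flen - l)]
      tail <- fr[(1L + l):flen]
      den <- sqrt(sum(head^2) * sum(tail^2))
      if (den <= 0) 0 else sum(head * tail) / den
    }, numeric(1))
    # among local maxima of r, prefer the smallest lag within tolerance of
    # the global maximum: integer multiples of the true period tie with it
    # (sub-harmonic / octave errors) and must not win on float dust
    rmax <- max(r)
    nl <- length(r)
    is_pk <- c(r[1L] > r[2L],
               r[2:(nl - 1L)] >= r[1:(nl - 2L)] & r[2:(nl - 1L)] >= r[3:nl],
               r[nl] > r[nl - 1L])
    cand_i <- which(is_pk & r >= rmax - 0.01 * max(rmax, 0.1))
    i <- if (length(cand_i)) cand_i[1L] else which.max(r)
    lag <- lags[i]
    rpk <- r[i]
    if (i > 1L && i < length(r)) {       # parabolic refinement
      denom <- r[i - 1L] - 2 * r[i] + r[i + 1L]
      if (denom < 0) {
        delta <- 0.5 * (r[i - 1L] - r[i + 1L]) / denom
        delta <- max(-1, min(1, delta))
        lag <- lags[i] + delta
        rpk <- r[i] - 0.25 * (r[i - 1L] - r[i + 1L]) * delta
      }
    }
    c(f0 = fs / lag, r = max(0, min(1, rpk)))
  })
  m <- do.call(rbind, res)
  data.frame(time_s = (starts - 1L + flen / 2) / fs,
             f0 = m[, "f0"], r = m[, "r"],
             voiced = is.finite(m[, "f0"]) & m[, "r"] >= voicing_threshold)
}

.f0_track_segment <- function(recording, interval, ...) {
  iv <- .as_interval(interval)
  x <- recording$samples[.segment_index(recording, iv$start_s, iv$end_s)]
  .f0_track(x, recording$sample_rate, ...)
}

#' Fundamental-frequency features of a segment
#'
#' Frame-wise f0 (0.04 s frames, 0.01 s hop, search band 50-400 Hz,
#' voicing threshold 0.3 on the normalized autocorrelation peak).
#' `first_f0`/`middle_f0`/`last_f0` are the f0 of the first, central and
#' last voiced frame; `median`/`mean`/`max`/`min`/`range` are over voiced
#' frames; `f0variation` is the population sd and `f0skew`/`f0kurt` the
#' population skewness/kurtosis of voiced f0. `slope_start2max` and
#' `slope_max2end` are the f0 rise and fall rates around the f0 maximum,
#' `(max_f0 - first_f0)/(t_max - t_first)` and
#' `(last_f0 - max_f0)/(t_last - t_max)`, normalized by `mean_f0` (units
#' 1/s); NA when the maximum sits at the segment edge. All fields are NA
#' for all-unvoiced segments.
#'
#' @param recording an [audio_recording()].
#' @param interval a [segment_interval()] spanning at least 2 f0 frames.
#' @return named list of the 13 f0 fields.
#' @export
f0_features <- function(recording, interval) {
  tr <- .f0_track_segment(recording, interval)
  v <- tr[tr$voiced, , drop = FALSE]
  empty <- stats::setNames(
    as.list(rep(NA_real_, 13L)),
    c("first_f0", "middle_f0", "last_f0", "median_f0", "mean_f0",
      "f0variation", "f0skew", "f0kurt", "max_f0", "min_f0", "range_f0",
      "slope_start2max", "slope_max2end"))
  if (nrow(v) == 0L) return(empty)
  f0 <- v$f0
  mom <- .pop_moments(f0)
  i_max <- which.max(f0)[1L]
  slope <- function(df0, dt) if (dt > 0) (df0 / dt) / mom$mean else NA_real_
  list(first_f0 = f0[1L],
       middle_f0 = f0[ceiling(length(f0) / 2)],
       last_f0 = f0[length(f0)],
       median_f0 = stats::median(f0),
       mean_f0 = mom$mean,
       f0variation = mom$sd,
       f0skew = mom$skew, f0kurt = mom$kurt,
       max_f0 = max(f0), min_f0 = min(f0),
       range_f0 = max(f0) - min(f0),
       slope_start2max = slope(max(f0) - f0[1L], v$time_s[i_max] - v$time_s[1L]),
       slope_max2end = slope(f0[length(f0)] - max(f0),
                             v$time_s[length(f0)] - v$time_s[i_max]))
}

#' Periodicity-quality features: jitter and HNR
#'
#' `jitter` is the mean absolute difference of consecutive voiced-frame
#' fundamental periods relative to the mean period, in percent; it needs
#' at least 2 voiced frames (else NA). `HNR` is
#' `10*log10(r / (1 - r))` dB, where `r` is the normalized-autocorrelation
#' peak averaged over voiced frames — or over all frames when nothing is
#' voiced, so aperiodic segments report a (negative) HNR rather than NA.
#'
#' @inheritParams f0_features
#' @return named list `jitter` (percent), `HNR` (dB).
#' @export
quality_features <- function(recording, interval) {
  tr <- .f0_track_segment(recording, interval)
  vidx <- which(tr$voiced)
  jitter <- NA_real_
  if (length(vidx) >= 2L) {
    consec <- vidx[which(diff(vidx) == 1L)]
    if (length(consec) >= 1L) {
      p <- 1 / tr$f0
      dp <- abs(p[consec + 1L] - p[consec])
      jitter <- 100 * mean(dp) / mean(p[vidx])
    }
  }
  r_bar <- if (length(vidx)) mean(tr$r[vidx]) else mean(tr$r)
  r_bar <- max(1e-12, min(1 - 1e-10, r_bar))
  list(jitter = jitter, HNR = 10 * log10(r_bar / (1 - r_bar)))
}

#' Harmonic-ratio features
#'
#' Per-frame harmonic ratio = the normalized-autocorrelation peak in the
#' f0 search band, clipped to \[0, 1\] — a periodicity score. The block is
#' its mean, median, population sd, max and min over all frames of the
#' segment.
#'
#' @inheritParams f0_features
#' @return named list `hr_mean`, `hr_median`, `hr_std`, `hr_max`, `hr_min`.
#' @export
hr_ratio_features <- function(recording, interval) {
  tr <- .f0_track_segment(recording, interval)
  r <- pmin(1, pmax(0, tr$r))
  list(hr_mean = mean(r), hr_median = stats::median(r),
       hr_std = .pop_moments(r)$sd, hr_max = max(r), hr_min = min(r))
}

#' Per-cycle duration table
#'
#' Durations of S1, S2, systole, diastole and the whole cycle, one row per
#' cardiac cycle, with a mean/sd summary across cycles in the `summary`
#' attribute.
#'
#' @param segmentation a nonempty [cycle_segmentation()].
#' @return data.frame of per-cycle durations (seconds); attribute
#'   `summary` holds the mean and (sample) sd rows.
#' @export
time_domain_features <- function(segmentation) {
  stopifnot(inherits(segmentation, "cycle_segmentation"))
  if (n_cycles(segmentation) == 0L)
    hs_error("hs_degenerate_segmentation", "empty segmentation")
  d <- cycle_durations(segmentation)
  num <- d[, c("s1", "s2", "systole", "diastole", "cycle_duration")]
  smry <- data.frame(statistic = c("mean", "sd"),
                     rbind(colMeans(num),
                           vapply(num, stats::sd, numeric(1))))
  attr(d, "summary") <- smry
  d
}

.feature_block <- function(recording, iv) {
  amp <- tryCatch(amplitude_features(recording, iv),
                  heartseg_error = function(e) list(
                    maxdb = NA_real_, mindb = NA_real_,
                    meandb = NA_real_, middledb = NA_real_))
  st <- tryCatch(stat_features(recording, iv),
                 heartseg_error = function(e)
                   stats::setNames(as.list(rep(NA_real_, 12L)),
                                   c("absomean", "STD", "skew", "kurt", "max",
                                     "min", "peak2valley", "RMS", "shapefactor",
                                     "impulsefactor", "marginfactor", "energy")))
  f0 <- tryCatch(f0_features(recording, iv),
                 heartseg_error = function(e)
                   stats::setNames(as.list(rep(NA_real_, 13L)),
                                   c("first_f0", "middle_f0", "last_f0",
                                     "median_f0", "mean_f0", "f0variation",
                                     "f0skew", "f0kurt", "max_f0", "min_f0",
                                     "range_f0", "slope_start2max",
                                     "slope_max2end")))
  ql <- tryCatch(quality_features(recording, iv),
                 heartseg_error = function(e)
                   list(jitter = NA_real_, HNR = NA_real_))
  hr <- tryCatch(hr_ratio_features(recording, iv),
                 heartseg_error = function(e)
                   stats::setNames(as.list(rep(NA_real_, 5L)),
                                   c("hr_mean", "hr_median", "hr_std",
                                     "hr_max", "hr_min")))
  c(amp, st, f0, ql, hr)
}

#' Full feature table for a segmented recording
#'
#' One row per segment per cycle (four rows per cycle), carrying the
#' duration, amplitude, shape-statistic, f0, quality and harmonic-ratio
#' blocks in a fixed column order, plus a per-state mean/sd summary in the
#' `summary` attribute. Segments whose feature computation fails are kept
#' as NA rows rather than aborting the table.
#'
#' @param recording the standardized [audio_recording()] the segmentation
#'   refers to.
#' @param segmentation a [cycle_segmentation()] (may be empty, giving a
#'   zero-row table).
#' @return data.frame with columns `cycle`, `state` (S1/systole/S2/
#'   diastole), `start_s`, `end_s`, `duration_s` and the 36 feature
#'   columns; attribute `summary` is a per-state data.frame of means and
#'   sds.
#' @export
extract_all <- function(recording, segmentation) {
  stopifnot(inherits(recording, "audio_recording"),
            inherits(segmentation, "cycle_segmentation"))
  feat_names <- c("maxdb", "mindb", "meandb", "middledb",
                  "absomean", "STD", "skew", "kurt", "max", "min",
                  "peak2valley", "RMS", "shapefactor", "impulsefactor",
                  "marginfactor", "energy",
                  "first_f0", "middle_f0", "last_f0", "median_f0", "mean_f0",
                  "f0variation", "f0skew", "f0kurt", "max_f0", "min_f0",
                  "range_f0", "slope_start2max", "slope_max2end",
                  "jitter", "HNR",
                  "hr_mean", "hr_median", "hr_std", "hr_max", "hr_min")
  if (nrow(segmentation) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(integer(), character(), numeric(), numeric(), numeric()),
        rep(list(numeric()), length(feat_names))),
      c("cycle", "state", "start_s", "end_s", "duration_s", feat_names)))
    attr(out, "summary") <- NULL
    return(out)
  }
  rows <- lapply(seq_len(nrow(segmentation)), function(i) {
    iv <- list(start_s = segmentation$start_s[i],
               end_s = segmentation$end_s[i],
               state = segmentation$state[i])
    blk <- .feature_block(recording, iv)
    cbind(data.frame(cycle = segmentation$cycle[i],
                     state = unname(.hs_state_labels[segmentation$state[i]]),
                     start_s = iv$start_s, end_s = iv$end_s,
                     duration_s = iv$end_s - iv$start_s,
                     stringsAsFactors = FALSE),
          as.data.frame(blk[c(feat_names)]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num_cols <- c("duration_s", feat_names)
  smry <- do.call(rbind, lapply(unname(.hs_state_labels), function(stt) {
    sub <- out[out$state == stt, num_cols, drop = FALSE]
    data.frame(state = stt,
               t(colMeans(sub, na.rm = TRUE)),
               stats::setNames(
                 as.data.frame(t(vapply(sub, function(col)
                   stats::sd(col, na.rm = TRUE), numeric(1)))),
                 paste0("sd_", num_cols)))
  }))
  names(smry)[2:(1 + length(num_cols))] <- paste0("mean_", num_cols)
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  out
}
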