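# Core segmentation algorithm: locate the S1 peak train on the Shannon
# envelope, find S2 between adjacent S1s, reject outlier S2 candidates,
# localize burst boundaries, and assemble four-state cycle labels.

#' Segmentation parameters
#'
#' All tunables of the segmenter in one validated container. Defaults are
#' documented per argument; every pipeline run records the full set.
#'
#' @param min_hr_bpm,max_hr_bpm plausible heart-rate band in beats/min
#'   (defaults 40 and 200). Candidate peak spacing and the cycle-period
#'   search are confined to `[60/max_hr, 60/min_hr]` seconds.
#' @param peak_rel_threshold fraction of the envelope maximum below which
#'   local maxima are not considered peak candidates (default 0.2).
#' @param boundary_fraction fraction of a peak's envelope height at which
#'   its segment boundary is placed (default 0.1), unless a significant
#'   valley is met first.
#' @param s2_outlier_k robust-deviation multiplier for S2 outlier rejection
#'   (default 3): candidates farther than `k` MAD-based standard deviations
#'   from the median in height or S1-to-S2 lag are dropped.
#' @return object of class `segmenter_params`.
#' @export
segmenter_params <- function(min_hr_bpm = 40, max_hr_bpm = 200,
                             peak_rel_threshold = 0.2,
                             boundary_fraction = 0.1,
                             s2_outlier_k = 3.0) {
  if (!is.finite(min_hr_bpm) || !is.finite(max_hr_bpm) ||
      min_hr_bpm <= 0 || min_hr_bpm >= max_hr_bpm)
    hs_error("hs_invalid_params", "need 0 < min_hr_bpm < max_hr_bpm")
  if (!is.finite(boundary_fraction) || boundary_fraction <= 0 ||
      boundary_fraction >= 1)
    hs_error("hs_invalid_params", "boundary_fraction must lie in (0, 1)")
  if (!is.finite(peak_rel_threshold) || peak_rel_threshold <= 0 ||
      peak_rel_threshold >= 1)
    hs_error("hs_invalid_params", "peak_rel_threshold must lie in (0, 1)")
  if (!is.finite(s2_outlier_k) || s2_outlier_k <= 0)
    hs_error("hs_invalid_params", "s2_outlier_k must be positive")
  structure(list(min_hr_bpm = min_hr_bpm, max_hr_bpm = max_hr_bpm,
                 peak_rel_threshold = peak_rel_threshold,
                 boundary_fraction = boundary_fraction,
                 s2_outlier_k = s2_outlier_k),
            class = "segmenter_params")
}

#' @export
print.segmenter_params <- function(x, ...) {
  cat(sprintf(
    "<segmenter_params> HR band [%g, %g] bpm; peak threshold %g; boundary fraction %g; S2 outlier k %g\n",
    x$min_hr_bpm, x$max_hr_bpm, x$peak_rel_threshold,
    x$boundary_fraction, x$s2_outlier_k))
  invisible(x)
}

# strict-left / gte-right local maxima (interior indices only)
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
}

# Energy-centroid refinement of a peak time over its half-height lobe.
# The Shannon transform is non-monotonic near full scale, so an S1 lobe's
# very top can flatten or split; the centroid of the lobe is a stabler
# location estimate than the argmax.
.refine_peak_time <- function(env, p, cap_s) {
  v <- env$values
  t <- envelope_times(env)
  half <- 0.5 * v[p]
  cap <- max(1L, round(cap_s / env$frame_hop_s))
  lo <- p
  while (lo > 1L && v[lo - 1L] >= half && (p - lo) < cap) lo <- lo - 1L
  hi <- p
  n <- length(v)
  while (hi < n && v[hi + 1L] >= half && (hi - p) < cap) hi <- hi + 1L
  w <- v[lo:hi] - half
  w[w < 0] <- 0
  if (sum(w) <= 0) return(t[p])
  sum(t[lo:hi] * w) / sum(w)
}

# Cycle-period estimate (seconds) from the envelope autocorrelation,
# searched over the plausible heart-rate band. Prefers the smallest lag
# whose (scaled) autocorrelation is a local maximum within 15% of the best,
# which guards against period doubling when two cycles fit the band.
.estimate_cycle_period <- function(env, params) {
  v <- env$values
  hop <- env$frame_hop_s
  n <- length(v)
  l_min <- max(1L, round((60 / params$max_hr_bpm) / hop))
  l_max <- min(n - 2L, round((60 / params$min_hr_bpm) / hop))
  if (l_max <= l_min) return(NA_real_)
  a <- v - mean(v)
  lags <- l_min:l_max
  r <- vapply(lags, function(l)
    sum(a[1:(n - l)] * a[(1 + l):n]) / (n - l), numeric(1))
  if (all(!is.finite(r)) || max(r) <= 0) return(NA_real_)
  is_lmax <- c(FALSE, r[2:(length(r) - 1L)] > r[1:(length(r) - 2L)] &
                 r[2:(length(r) - 1L)] >= r[3:length(r)], FALSE)
  good <- which(is_lmax & r >= 0.85 * max(r))
  idx <- if (length(good)) good[1L] else which.max(r)
  lags[idx] * hop
}

# Greedy periodic chaining: starting from the anchor candidate, step by the
# period estimate in both directions and pick the tallest candidate inside
# each +/- 25% window; windows with no candidate are skipped.
.chain_candidates <- function(cand, anchor_i, period, t_max) {
  win <- 0.25 * period
  sel <- anchor_i
  # forward
  pos <- cand$time_s[anchor_i]
  while (pos + period - win <= t_max) {
    target <- pos + period
    in_win <- which(abs(cand$time_s - target) <= win)
    if (length(in_win)) {
      pick <- in_win[which.max(cand$height[in_win])]
      sel <- c(sel, pick)
      pos <- cand$time_s[pick]
    } else pos <- target
  }
  # backward
  pos <- cand$time_s[anchor_i]
  while (pos - period + win >= 0) {
    target <- pos - period
    in_win <- which(abs(cand$time_s - target) <= win)
    if (length(in_win)) {
      pick <- in_win[which.max(cand$height[in_win])]
      sel <- c(sel, pick)
      pos <- cand$time_s[pick]
    } else pos <- target
  }
  sort(unique(sel))
}

# Highest interior envelope maximum strictly between two times, excluding a
# margin next to each endpoint (the flanking peaks' own lobes).
.interior_maximum <- function(env, t_left, t_right) {
  t <- envelope_times(env)
  gap <- t_right - t_left
  margin <- max(0.15 * gap, env$frame_len_s)
  keep <- which(t > t_left + margin & t < t_right - margin)
  if (length(keep) < 3L) return(NULL)
  v <- env$values
  lm <- .local_maxima(v)
  lm <- lm[lm %in% keep & v[lm] > 0]
  if (!length(lm)) return(NULL)
  p <- lm[which.max(v[lm])]
  list(index = p, time_s = t[p], height = v[p])
}

#' Detect the S1 peak train on an envelope
#'
#' Finds candidate local maxima above `peak_rel_threshold` times the
#' envelope maximum, merges candidates closer than the shortest plausible
#' cycle (`60/max_hr_bpm` s, keeping the taller), estimates the cycle
#' period from the envelope autocorrelation, and extracts the dominant
#' quasi-periodic train by greedy periodic chaining from the strongest
#' candidate. If the interior maxima between train peaks sit in the latter
#' half of the gaps, the train is taken to be S2 (systole is the shorter
#' cycle fraction) and the assignment is swapped. Peak times are refined by
#' the half-height energy centroid of each lobe.
#'
#' @param envelope a [pcg_envelope()] from a standardized recording.
#' @param params a [segmenter_params()].
#' @return data.frame with columns `time_s`, `height`, `kind` (`"S1"`),
#'   time-ordered.
#' @export
detect_s1_peaks <- function(envelope, params = segmenter_params()) {
  stopifnot(inherits(envelope, "pcg_envelope"))
  v <- envelope$values
  if (length(v) == 0L)
    hs_error("hs_no_peaks", "empty envelope")
  t <- envelope_times(envelope)
  vmax <- max(v)
  lm <- .local_maxima(v)
  lm <- lm[v[lm] >= params$peak_rel_threshold * vmax]
  if (vmax <= 0 || length(lm) == 0L)
    hs_error("hs_no_peaks", "no candidate peaks above threshold (silent or featureless envelope)")

  # merge maxima belonging to the same burst lobe (the Shannon transform
  # can split a lobe's top into two shoulders), tallest first
  merge_sep <- max(3 * envelope$frame_len_s, 0.06)
  ord <- lm[order(v[lm], decreasing = TRUE)]
  kept <- integer()
  for (p in ord) {
    if (!length(kept) || all(abs(t[p] - t[kept]) >= merge_sep))
      kept <- c(kept, p)
  }
  kept <- sort(kept)
  cand <- data.frame(index = kept, time_s = t[kept], height = v[kept])

  if (nrow(cand) <= 2L) {
    sel <- cand
  } else {
    period <- .estimate_cycle_period(envelope, params)
    if (!is.finite(period))
      period <- stats::median(diff(cand$time_s))

    # phase hypotheses: chain a periodic train from each early candidate
    # (plus the global maximum) and keep the best-covering trains
    anchors <- unique(c(which(cand$time_s < min(cand$time_s) + 2 * period),
                        which.max(cand$height)))
    trains <- unique(lapply(anchors, function(a)
      .chain_candidates(cand, a, period, max(t))))
    sizes <- lengths(trains)
    trains <- trains[sizes >= 0.75 * max(sizes) & sizes >= 2L]
    # among complete trains, pick the one with the most regular
    # inter-peak intervals (minimum coefficient of variation)
    score <- vapply(trains, function(tr) {
      dd <- diff(cand$time_s[tr])
      stats::sd(dd) / mean(dd)
    }, numeric(1))
    best <- which(score <= min(score) + 1e-9)
    if (length(best) > 1L) {   # tie: taller train wins
      med_h <- vapply(trains[best], function(tr)
        stats::median(cand$height[tr]), numeric(1))
      best <- best[which.max(med_h)]
    }
    sel <- cand[trains[[best[1L]]], , drop = FALSE]

    # S1-vs-S2 disambiguation: if the interior maxima between train peaks
    # sit in the latter half of the gaps, the train is the S2 train
    # (systole is the shorter cycle fraction); rebuild from the
    # complementary peaks. Near-ties go to the taller train as S1.
    if (nrow(sel) >= 2L) {
      fracs <- c(); int_t <- c(); int_h <- c()
      for (k in seq_len(nrow(sel) - 1L)) {
        im <- .interior_maximum(envelope, sel$time_s[k], sel$time_s[k + 1L])
        if (!is.null(im)) {
          fracs <- c(fracs, (im$time_s - sel$time_s[k]) /
                       (sel$time_s[k + 1L] - sel$time_s[k]))
          int_t <- c(int_t, im$time_s)
          int_h <- c(int_h, im$height)
        }
      }
      swap <- length(fracs) > 0 && stats::median(fracs) > 0.5
      if (length(fracs) > 0 && abs(stats::median(fracs) - 0.5) < 0.05)
        swap <- stats::median(int_h) > stats::median(sel$height)
      if (swap) {
        near <- vapply(int_t, function(ti) which.min(abs(cand$time_s - ti)),
                       integer(1))
        anchor2 <- near[which.max(cand$height[near])]
        sel <- cand[.chain_candidates(cand, anchor2, period, max(t)), ,
                    drop = FALSE]
      }
    }
  }

  cap <- 0.2 * (if (nrow(sel) >= 2L) stats::median(diff(sel$time_s)) else 1)
  times <- vapply(sel$index, function(p)
    .refine_peak_time(envelope, p, cap), numeric(1))
  out <- data.frame(time_s = times, height = sel$height, kind = "S1",
                    stringsAsFactors = FALSE)
  out[order(out$time_s), , drop = FALSE]
}

#' Detect S2 candidates between adjacent S1 peaks
#'
#' For each adjacent S1 pair, returns the highest interior envelope maximum
#' (excluding a margin around the S1 lobes themselves) as that cycle's S2
#' candidate, with its lag from the preceding S1. Cycles with no interior
#' maximum are returned as flagged missing-S2 placeholders (NA time).
#'
#' @param envelope a [pcg_envelope()].
#' @param s1_peaks output of [detect_s1_peaks()]; needs >= 2 rows.
#' @param params a [segmenter_params()].
#' @return data.frame with columns `cycle`, `time_s`, `height`, `lag_s`,
#'   `missing`, `kind` (`"S2"`).
#' @export
detect_s2_peaks <- function(envelope, s1_peaks, params = segmenter_params()) {
  stopifnot(inherits(envelope, "pcg_envelope"))
  if (!is.data.frame(s1_peaks) || nrow(s1_peaks) < 2L)
    hs_error("hs_insufficient_cycles", "need at least 2 S1 peaks to search for S2")
  n <- nrow(s1_peaks) - 1L
  rows <- vector("list", n)
  cap0 <- 0.2 * stats::median(diff(s1_peaks$time_s))
  for (k in seq_len(n)) {
    im <- .interior_maximum(envelope, s1_peaks$time_s[k],
                            s1_peaks$time_s[k + 1L])
    if (is.null(im)) {
      rows[[k]] <- data.frame(cycle = k, time_s = NA_real_, height = NA_real_,
                              lag_s = NA_real_, missing = TRUE, kind = "S2",
                              stringsAsFactors = FALSE)
    } else {
      tt <- .refine_peak_time(envelope, im$index, cap0)
      rows[[k]] <- data.frame(cycle = k, time_s = tt, height = im$height,
                              lag_s = tt - s1_peaks$time_s[k],
                              missing = FALSE, kind = "S2",
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Filter outlier S2 candidates
#'
#' Operationalizes "large difference from the average" robustly: a
#' candidate is dropped when its envelope height or its S1-to-S2 lag
#' deviates from the median by more than `s2_outlier_k` robust standard
#' deviations (median absolute deviation scaled by 1.4826). Needs at least
#' 3 non-missing candidates; with fewer, candidates pass through with a
#' warning. Surviving rows are returned unchanged.
#'
#' @param s2_peaks output of [detect_s2_peaks()].
#' @param params a [segmenter_params()].
#' @return the surviving rows of `s2_peaks` (missing-S2 placeholders are
#'   kept); attribute `removed_cycles` lists the cycles whose candidate was
#'   rejected.
#' @export
filter_s2_outliers <- function(s2_peaks, params = segmenter_params()) {
  stopifnot(is.data.frame(s2_peaks))
  real <- which(!s2_peaks$missing)
  if (length(real) < 3L) {
    hs_warn("hs_too_few_s2",
            "fewer than 3 S2 candidates; outlier rule skipped (passthrough)")
    attr(s2_peaks, "removed_cycles") <- integer()
    return(s2_peaks)
  }
  robust_dev <- function(x, floor) {
    med <- stats::median(x)
    sigma <- 1.4826 * stats::median(abs(x - med))
    # floor the robust sigma at the measurement resolution: in clean
    # recordings the MAD collapses toward zero and would flag deviations
    # far below what the envelope can actually resolve
    sigma <- max(sigma, floor)
    abs(x - med) / sigma
  }
  h <- s2_peaks$height[real]
  dev_h <- robust_dev(h, 0.02 * stats::median(h))  # 2% of typical height
  dev_l <- robust_dev(s2_peaks$lag_s[real], 0.01)  # envelope hop, seconds
  bad <- real[dev_h > params$s2_outlier_k | dev_l > params$s2_outlier_k]
  if (length(bad) == length(real))
    hs_error("hs_degenerate_segmentation",
             "all S2 candidates rejected as outliers")
  out <- s2_peaks[!seq_len(nrow(s2_peaks)) %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_cycles") <- s2_peaks$cycle[bad]
  out
}

#' Locate a segment boundary interval around an envelope peak
#'
#' Scanning outward from the peak, the boundary on each side is the first
#' event met: either the envelope crossing `boundary_fraction` times the
#' peak height (linearly interpolated between frames) or a significant
#' local valley (a local minimum at or below half the peak height; ripple
#' on top of the lobe does not count). If the envelope edge is reached
#' without either event, the boundary clips to the envelope span and the
#' result is flagged.
#'
#' @param envelope a [pcg_envelope()].
#' @param peak one-row data.frame or list with `time_s`, `height` and
#'   `kind` (`"S1"` or `"S2"`).
#' @param params a [segmenter_params()].
#' @return a [segment_interval()] containing the peak; attribute `clipped`
#'   is TRUE when an edge was hit.
#' @export
locate_boundaries <- function(envelope, peak, params = segmenter_params()) {
  stopifnot(inherits(envelope, "pcg_envelope"))
  v <- envelope$values
  t <- envelope_times(envelope)
  n <- length(v)
  p <- which.min(abs(t - peak$time_s))
  h <- max(peak$height, v[p])
  thr <- params$boundary_fraction * h
  valley_lvl <- 0.5 * h

  scan <- function(dir) {
    i <- p
    repeat {
      j <- i + dir
      if (j < 1L || j > n) return(list(t = t[i], clipped = TRUE))
      if (v[j] < thr) {
        # linear interpolation of the crossing between frames j and i
        frac <- (v[i] - thr) / (v[i] - v[j])
        return(list(t = t[i] + frac * (t[j] - t[i]), clipped = FALSE))
      }
      jj <- j + dir
      if (jj >= 1L && jj <= n &&
          v[j] <= valley_lvl && v[j] < v[i] && v[j] <= v[jj]) {
        return(list(t = t[j], clipped = FALSE))   # significant valley
      }
      i <- j
    }
  }
  left <- scan(-1L)
  right <- scan(+1L)
  start_s <- max(0, min(left$t, peak$time_s - 1e-9))
  end_s <- max(right$t, peak$time_s + 1e-9)
  iv <- segment_interval(start_s, end_s, peak$kind)
  attr(iv, "clipped") <- left$clipped || right$clipped
  iv
}

#' Assemble four-state cycle labels from S1 and S2 intervals
#'
#' Per cycle `k`: systole spans S1_k onset to S2_k onset, diastole spans
#' S2_k onset to S1_(k+1) onset, with the S1/S2 intervals embedded (ends
#' clipped to the state boundary if the located burst interval overruns
#' it). The last S1 closes the final cycle and starts none of its own.
#' Cycles without an S2 onset between their flanking S1 onsets are dropped
#' from the cycle list and reported via the `missing_s2` attribute.
#'
#' @param s1_intervals list of S1 [segment_interval()]s (>= 2), onset-ordered
#'   or not.
#' @param s2_intervals list of S2 [segment_interval()]s.
#' @return a [cycle_segmentation()]; attribute `missing_s2` holds the
#'   (original) indices of cycles dropped for lack of an S2.
#' @export
build_cycle_labels <- function(s1_intervals, s2_intervals) {
  as_df <- function(lst, st) {
    if (!length(lst)) return(data.frame(start_s = numeric(), end_s = numeric()))
    stopifnot(all(vapply(lst, function(x) inherits(x, "segment_interval"),
                         logical(1))))
    stopifnot(all(vapply(lst, function(x) x$state == st, logical(1))))
    data.frame(start_s = vapply(lst, `[[`, numeric(1), "start_s"),
               end_s = vapply(lst, `[[`, numeric(1), "end_s"))
  }
  s1 <- as_df(s1_intervals, "S1")
  s2 <- as_df(s2_intervals, "S2")
  if (nrow(s1) < 2L)
    hs_error("hs_insufficient_cycles", "need at least 2 S1 intervals")
  s1 <- s1[order(s1$start_s), , drop = FALSE]
  s2 <- s2[order(s2$start_s), , drop = FALSE]
  if (nrow(s2) > 0L && any(s2$start_s < s1$start_s[1L]))
    hs_error("hs_sequencing_error",
             "S2 onset before the first S1 onset (non-alternating sequence)")

  rows <- list(); missing <- integer(); cyc <- 0L
  for (k in seq_len(nrow(s1) - 1L)) {
    a <- s1$start_s[k]; b <- s1$start_s[k + 1L]
    in_gap <- which(s2$start_s > a & s2$start_s < b)
    if (length(in_gap) > 1L)
      hs_error("hs_sequencing_error", sprintf(
        "cycle %d holds %d S2 onsets (non-alternating sequence)",
        k, length(in_gap)))
    if (length(in_gap) == 0L) { missing <- c(missing, k); next }
    j <- in_gap
    cyc <- cyc + 1L
    rows[[cyc]] <- data.frame(
      cycle = cyc, state = .hs_states,
      start_s = c(a, a, s2$start_s[j], s2$start_s[j]),
      end_s = c(min(s1$end_s[k], s2$start_s[j]), s2$start_s[j],
                min(s2$end_s[j], b), b),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    hs_error("hs_degenerate_segmentation", "no complete cycles could be formed")
  seg <- cycle_segmentation(do.call(rbind, rows))
  attr(seg, "missing_s2") <- missing
  seg
}

#' Physiological sanity report for a segmentation
#'
#' Checks, without mutating the segmentation: (i) the mean S1 duration is
#' at least the mean S2 duration across the recording; (ii) every S2 onset
#' lies strictly between its flanking S1 onsets; (iii) every cycle duration
#' falls in the plausible heart-rate band; and, when a feature summary with
#' `mean_f0` per state is supplied, (iv) S1/S2 fundamental frequencies lie
#' in a physiological 20-500 Hz range.
#'
#' @param segmentation a nonempty [cycle_segmentation()].
#' @param feature_summary optional data.frame with columns `state` and
#'   `mean_f0` (Hz), e.g. the summary from [extract_all()].
#' @param params a [segmenter_params()] (heart-rate band).
#' @return object of class `physiology_report`: list with `per_cycle`
#'   (data.frame of pass/fail per cycle), `s1_longer_than_s2`, `f0_in_band`
#'   (NA when not checked) and `all_pass`.
#' @export
validate_physiology <- function(segmentation, feature_summary = NULL,
                                params = segmenter_params()) {
  stopifnot(inherits(segmentation, "cycle_segmentation"))
  if (n_cycles(segmentation) == 0L)
    hs_error("hs_degenerate_segmentation", "empty segmentation")
  d <- cycle_durations(segmentation)
  lo <- 60 / params$max_hr_bpm; hi <- 60 / params$min_hr_bpm
  s2_rows <- segmentation[segmentation$state == "S2", , drop = FALSE]
  s1_rows <- segmentation[segmentation$state == "S1", , drop = FALSE]
  dia_rows <- segmentation[segmentation$state == "DIASTOLE", , drop = FALSE]
  per_cycle <- data.frame(
    cycle = d$cycle,
    s2_inside_flanks = s2_rows$start_s > s1_rows$start_s &
      s2_rows$start_s < dia_rows$end_s,
    rate_band = d$cycle_duration >= lo & d$cycle_duration <= hi
  )
  s1_ge_s2 <- mean(d$s1) >= mean(d$s2)
  f0_ok <- NA
  f0_col <- intersect(c("mean_f0", "mean_mean_f0"), names(feature_summary))
  if (!is.null(feature_summary) && "state" %in% names(feature_summary) &&
      length(f0_col)) {
    f0s <- feature_summary[[f0_col[1L]]][feature_summary$state %in% c("S1", "S2")]
    f0s <- f0s[is.finite(f0s)]
    f0_ok <- length(f0s) == 0L || all(f0s >= 20 & f0s <= 500)
  }
  structure(list(per_cycle = per_cycle,
                 s1_longer_than_s2 = s1_ge_s2,
                 f0_in_band = f0_ok,
                 all_pass = s1_ge_s2 &&
                   all(per_cycle$s2_inside_flanks) &&
                   all(per_cycle$rate_band) &&
                   (is.na(f0_ok) || f0_ok)),
            class = "physiology_report")
}

#' @export
print.physiology_report <- function(x, ...) {
  cat("<physiology_report>\n")
  cat("  mean S1 duration >= mean S2 duration:",
      if (x$s1_longer_than_s2) "pass" else "FAIL", "\n")
  cat(sprintf("  S2 inside flanking S1 onsets: %d/%d cycles\n",
              sum(x$per_cycle$s2_inside_flanks), nrow(x$per_cycle)))
  cat(sprintf("  cycle duration in rate band:  %d/%d cycles\n",
              sum(x$per_cycle$rate_band), nrow(x$per_cycle)))
  if (!is.na(x$f0_in_band))
    cat("  S1/S2 f0 physiological:", if (x$f0_in_band) "pass" else "FAIL", "\n")
  cat("  overall:", if (x$all_pass) "pass" else "FAIL", "\n")
  invisible(x)
}
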