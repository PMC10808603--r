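make_fit_inputs <- function(cfg) {
  g <- generate_pcg(cfg)
  rec_filt <- standardize(bandpass(standardize(g$recording), 25, 400))
  list(g = g, env = shannon_envelope(rec_filt))
}

test_that("S1 peaks land within 10 ms of the true burst centers", {
  cfg <- synthetic_pcg_config(heart_rate_bpm = 72, duration_s = 20,
                              snr_db = 20, seed = 2)
  inp <- make_fit_inputs(cfg)
  s1 <- detect_s1_peaks(inp$env)
  truth_s1 <- inp$g$truth[inp$g$truth$state == "S1", ]
  centers <- (truth_s1$start_s + truth_s1$end_s) / 2
  # the S1 closing the final cycle is rendered too; it may be detected
  closing <- max(inp$g$truth$end_s) + cfg$s1_duration_s / 2
  expect_true(nrow(s1) %in% c(length(centers), length(centers) + 1L))
  err <- vapply(s1$time_s, function(x) min(abs(x - c(centers, closing))),
                numeric(1))
  expect_lt(max(err), 0.010)
})

test_that("degenerate envelopes raise the no-peaks error", {
  flat <- pcg_envelope(numeric(200), 0.01, 0.02, 0.01)
  expect_error(detect_s1_peaks(flat), class = "hs_no_peaks")
  expect_error(detect_s1_peaks(pcg_envelope(numeric(0), 0.01, 0.02, 0.01)),
               class = "hs_no_peaks")
})

test_that("a single burst yields exactly one peak", {
  fs <- 4000
  t <- (0:(2 * fs - 1)) / fs
  x <- exp(-(t - 1)^2 / (2 * 0.03^2)) * sin(2 * pi * 80 * (t - 1))
  env <- shannon_envelope(standardize(audio_recording(x, fs)))
  s1 <- detect_s1_peaks(env)
  expect_identical(nrow(s1), 1L)
  expect_equal(s1$time_s, 1, tolerance = 0.02)
})

test_that("S2 is found between adjacent S1s; silent interiors are flagged", {
  cfg <- synthetic_pcg_config(heart_rate_bpm = 72, duration_s = 20,
                              s2_onset_fraction = 0.36, snr_db = 20, seed = 3)
  inp <- make_fit_inputs(cfg)
  s1 <- detect_s1_peaks(inp$env)
  s2 <- detect_s2_peaks(inp$env, s1)
  truth_s2 <- inp$g$truth[inp$g$truth$state == "S2", ]
  centers <- (truth_s2$start_s + truth_s2$end_s) / 2
  got <- s2$time_s[!s2$missing]
  err <- vapply(got, function(x) min(abs(x - centers)), numeric(1))
  expect_lt(max(err), 0.010)
  expect_error(detect_s2_peaks(inp$env, s1[1, , drop = FALSE]),
               class = "hs_insufficient_cycles")

  # two isolated bursts with a silent interior -> missing-S2 placeholder
  fs <- 4000
  t <- (0:(3 * fs - 1)) / fs
  x <- exp(-(t - 0.5)^2 / (2 * 0.03^2)) * sin(2 * pi * 80 * t) +
    exp(-(t - 2.5)^2 / (2 * 0.03^2)) * sin(2 * pi * 80 * t)
  env <- shannon_envelope(standardize(audio_recording(x, fs)))
  s1b <- detect_s1_peaks(env)
  s2b <- detect_s2_peaks(env, s1b)
  expect_true(all(s2b$missing))
})

test_that("the MAD rule removes lag outliers and keeps identical candidates", {
  mk <- function(lags, heights) {
    data.frame(cycle = seq_along(lags), time_s = cumsum(rep(0.83, length(lags))) + lags,
               height = heights, lag_s = lags, missing = FALSE, kind = "S2")
  }
  ten <- mk(rep(0.30, 10), rep(1, 10))
  kept <- filter_s2_outliers(ten)
  expect_identical(nrow(kept), 10L)
  expect_length(attr(kept, "removed_cycles"), 0L)

  lags <- c(rep(0.30, 9), 0.60)
  set.seed(4)
  mixed <- mk(lags, 1 + rnorm(10, sd = 0.01))
  kept2 <- filter_s2_outliers(mixed)
  expect_identical(attr(kept2, "removed_cycles"), 10L)
  expect_identical(nrow(kept2), 9L)

  two <- mk(c(0.3, 0.31), c(1, 1))
  expect_warning(out <- filter_s2_outliers(two), class = "hs_too_few_s2")
  expect_identical(nrow(out), 2L)
})

test_that("boundary localization matches the triangular-envelope geometry", {
  # triangle of height 1 rising/falling over 0.1 s on a 1 ms grid
  hop <- 0.001
  up <- seq(0, 1, length.out = 101)
  vals <- c(numeric(100), up, rev(up)[-1], numeric(100))
  env <- pcg_envelope(vals, hop, hop, 0)
  apex <- (which.max(vals) - 1) * hop
  pk <- list(time_s = apex, height = 1, kind = "S1")
  iv <- locate_boundaries(env, pk, segmenter_params(boundary_fraction = 0.1))
  expect_equal(iv$end_s - iv$start_s, 0.18, tolerance = 1e-9)
  expect_equal((iv$start_s + iv$end_s) / 2, apex, tolerance = 1e-9)

  # boundary_fraction near 1 collapses the interval toward the apex
  iv2 <- locate_boundaries(env, pk, segmenter_params(boundary_fraction = 0.95))
  expect_lt(iv2$end_s - iv2$start_s, 0.02)
  expect_true(iv2$start_s < apex && apex < iv2$end_s)

  # peak at the envelope edge: clipped and flagged
  vals3 <- c(1, rev(up)[-1], numeric(50))
  env3 <- pcg_envelope(vals3, hop, hop, 0)
  iv3 <- locate_boundaries(env3, list(time_s = 0, height = 1, kind = "S1"))
  expect_equal(iv3$start_s, 0)
  expect_true(attr(iv3, "clipped"))
})

test_that("cycle labels follow the systole/diastole state definitions", {
  s1 <- list(segment_interval(0, 0.12, "S1"),
             segment_interval(0.83, 0.95, "S1"))
  s2 <- list(segment_interval(0.30, 0.42, "S2"))
  seg <- build_cycle_labels(s1, s2)
  expect_identical(n_cycles(seg), 1L)
  d <- cycle_durations(seg)
  expect_equal(d$systole, 0.30)
  expect_equal(d$diastole, 0.53)
  expect_identical(d$systole + d$diastole, d$cycle_duration)
  expect_equal(d$cycle_duration, 0.83)

  # S2 before its S1 onset
  late <- list(segment_interval(0.5, 0.62, "S1"),
               segment_interval(1.33, 1.45, "S1"))
  expect_error(build_cycle_labels(late, list(segment_interval(0.1, 0.2, "S2"))),
               class = "hs_sequencing_error")
  # two S2 onsets inside one cycle
  expect_error(build_cycle_labels(
    s1, list(segment_interval(0.3, 0.4, "S2"), segment_interval(0.5, 0.6, "S2"))),
    class = "hs_sequencing_error")
  expect_error(build_cycle_labels(s1[1], s2), class = "hs_insufficient_cycles")
})

test_that("physiology checks pass on simulator output and fail when violated", {
  cfg <- synthetic_pcg_config(heart_rate_bpm = 72, duration_s = 15,
                              snr_db = 20, seed = 6)
  g <- generate_pcg(cfg)
  fit <- segment_pcg(g$recording)
  expect_true(fit$validation$all_pass)

  # hand-built: S2 longer than S1
  rows <- data.frame(
    cycle = rep(1:2, each = 4),
    state = rep(c("S1", "SYSTOLE", "S2", "DIASTOLE"), 2),
    start_s = c(0, 0, 0.3, 0.3, 0.8, 0.8, 1.1, 1.1),
    end_s = c(0.05, 0.3, 0.5, 0.8, 0.85, 1.1, 1.3, 1.6))
  bad <- validate_physiology(cycle_segmentation(rows))
  expect_false(bad$s1_longer_than_s2)

  # 2.0 s cycle is below the 40 bpm floor
  slow <- data.frame(cycle = 1, state = c("S1", "SYSTOLE", "S2", "DIASTOLE"),
                     start_s = c(0, 0, 0.9, 0.9), end_s = c(0.1, 0.9, 1.0, 2.0))
  rep_slow <- validate_physiology(cycle_segmentation(slow))
  expect_false(all(rep_slow$per_cycle$rate_band))
})

test_that("segmentation is deterministic, conservative, and scale-invariant", {
  cfg <- synthetic_pcg_config(heart_rate_bpm = 80, duration_s = 15,
                              snr_db = 15, seed = 11)
  g <- generate_pcg(cfg)
  f1 <- segment_pcg(g$recording)
  f2 <- segment_pcg(g$recording)
  expect_identical(as.data.frame(f1$segmentation), as.data.frame(f2$segmentation))

  # sum of systole+diastole equals the span from first S1 to last cycle end
  d <- cycle_durations(f1$segmentation)
  miss <- f1$missing_s2_cycles
  expect_identical(d$systole + d$diastole, d$cycle_duration)
  if (length(miss) == 0) {
    expect_equal(sum(d$systole) + sum(d$diastole),
                 max(f1$segmentation$end_s) - min(f1$segmentation$start_s),
                 tolerance = 1e-12)
  }

  scaled <- audio_recording(0.137 * g$recording$samples, g$recording$sample_rate)
  f3 <- segment_pcg(scaled)
  expect_equal(as.data.frame(f3$segmentation), as.data.frame(f1$segmentation),
               tolerance = 1e-12)
})
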