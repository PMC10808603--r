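test_that("cycle count and length follow the configuration", {
  cfg <- synthetic_pcg_config(heart_rate_bpm = 72, duration_s = 10,
                              cycle_jitter_pct = 0, snr_db = Inf, seed = 1)
  g <- generate_pcg(cfg)
  expect_identical(n_cycles(g$truth), 12L)
  d <- cycle_durations(g$truth)
  expect_equal(d$cycle_duration, rep(60 / 72, 12), tolerance = 1e-9)
  expect_identical(length(g$recording$samples), 40000L)
})

test_that("generation is deterministic in the seed", {
  cfg <- synthetic_pcg_config(duration_s = 5, snr_db = 15, seed = 99)
  g1 <- generate_pcg(cfg)
  g2 <- generate_pcg(cfg)
  expect_identical(g1$recording$samples, g2$recording$samples)
  expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))
  g3 <- generate_pcg(synthetic_pcg_config(duration_s = 5, snr_db = 15, seed = 100))
  expect_false(identical(g1$recording$samples, g3$recording$samples))
})

test_that("truth labels satisfy every cycle-segmentation invariant", {
  for (seed in 1:5) {
    cfg <- synthetic_pcg_config(heart_rate_bpm = 55 + 17 * seed, duration_s = 8,
                                cycle_jitter_pct = 2, snr_db = 10, seed = seed)
    g <- generate_pcg(cfg)
    expect_s3_class(g$truth, "cycle_segmentation")  # constructor validates
    d <- cycle_durations(g$truth)
    expect_identical(d$systole + d$diastole, d$cycle_duration)
    expect_true(all(d$s1 <= d$systole & d$s2 <= d$diastole))
  }
})

test_that("noise-free generation standardizes to full scale", {
  g <- generate_pcg(synthetic_pcg_config(duration_s = 5, snr_db = Inf, seed = 2))
  expect_identical(max(abs(standardize(g$recording)$samples)), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_pcg_config(heart_rate_bpm = 30), class = "hs_invalid_config")
  expect_error(synthetic_pcg_config(duration_s = 1), class = "hs_invalid_config")
  expect_error(synthetic_pcg_config(s2_onset_fraction = 1.2),
               class = "hs_invalid_config")
  expect_error(synthetic_pcg_config(s1_duration_s = 0.5, s2_duration_s = 0.5),
               class = "hs_invalid_config")
})

test_that("murmur injection raises RMS only in the chosen phase", {
  g <- generate_pcg(synthetic_pcg_config(duration_s = 8, snr_db = Inf, seed = 3))
  same <- add_murmur(g$recording, g$truth, rel_level = 0)
  expect_identical(same$samples, g$recording$samples)

  rms_in <- function(rec, seg, state) {
    fs <- rec$sample_rate
    tvec <- (seq_along(rec$samples) - 1) / fs
    rows <- seg[seg$state == state, ]
    keep <- logical(length(tvec))
    for (i in seq_len(nrow(rows)))
      keep <- keep | (tvec >= rows$start_s[i] & tvec < rows$end_s[i])
    sqrt(mean(rec$samples[keep]^2))
  }
  with_m <- add_murmur(g$recording, g$truth, band_hz = c(150, 400),
                       rel_level = 0.2, phase = "SYSTOLE", seed = 4)
  expect_gt(rms_in(with_m, g$truth, "SYSTOLE"), rms_in(g$recording, g$truth, "SYSTOLE"))
  expect_equal(rms_in(with_m, g$truth, "DIASTOLE"),
               rms_in(g$recording, g$truth, "DIASTOLE"), tolerance = 1e-9)
  expect_error(add_murmur(g$recording, g$truth, phase = "S3"),
               class = "hs_unknown_phase")
})

test_that("heart rate is recovered within 1 bpm across seeds and rates", {
  for (seed in 1:5) {
    hr_true <- c(60, 72, 85, 95, 100)[seed]
    g <- generate_pcg(synthetic_pcg_config(heart_rate_bpm = hr_true,
                                           duration_s = 20, snr_db = 10,
                                           seed = seed))
    fit <- segment_pcg(g$recording)
    expect_lte(abs(fit$hr_bpm - hr_true), 1)
  }
})
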