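test_that("standardize removes DC and normalizes the peak to 1", {
  rec <- audio_recording(c(0.25, -0.25, 0.1, -0.1), 100)
  out <- standardize(rec)
  expect_equal(mean(out$samples), 0, tolerance = 1e-12)
  expect_equal(max(abs(out$samples)), 1)
  # mean removal happens before peak scaling
  rec2 <- audio_recording(c(0.25, -0.5), 100)
  out2 <- standardize(rec2)
  expect_equal(out2$samples, c(1, -1))      # [0.375, -0.375] scaled
  # already standardized input is a fixed point
  expect_equal(standardize(out)$samples, out$samples, tolerance = 1e-12)
})

test_that("standardize is idempotent and rejects silence", {
  set.seed(1)
  rec <- audio_recording(rnorm(500) + 3, 1000)
  once <- standardize(rec)
  twice <- standardize(once)
  expect_equal(twice$samples, once$samples, tolerance = 1e-12)
  expect_error(standardize(audio_recording(numeric(100), 1000)),
               class = "hs_silent_input")
})

test_that("band-pass rejects stopband tones and passes passband tones", {
  rms <- function(x) sqrt(mean(x^2))
  lo <- make_sine(10, 2, fs = 4000)
  out_lo <- bandpass(lo, 25, 400)
  expect_lt(rms(out_lo$samples), 0.05 * rms(lo$samples))
  mid <- make_sine(100, 2, fs = 4000)
  out_mid <- bandpass(mid, 25, 400)
  expect_equal(rms(out_mid$samples), rms(mid$samples), tolerance = 0.05)
  expect_length(out_mid$samples, length(mid$samples))
  expect_error(bandpass(mid, 400, 25), class = "hs_invalid_band")
  expect_error(bandpass(mid, 25, 3000), class = "hs_invalid_band")
})

test_that("Shannon envelope matches closed forms on constant signals", {
  fs <- 1000
  z <- audio_recording(rep(1e-300, fs), fs)  # effectively silent, nonzero container
  z$samples <- numeric(fs)
  env0 <- shannon_envelope(z)
  expect_true(all(env0$values == 0))
  # |x| = e^(-1/2): per-sample Shannon energy -x^2 ln(x^2) = e^(-1)
  c1 <- audio_recording(rep(exp(-0.5), fs), fs)
  env1 <- shannon_envelope(c1)
  expect_equal(env1$values, rep(exp(-1), length(env1$values)), tolerance = 1e-12)
  # |x| = 1: -1 * ln(1) = 0
  c2 <- audio_recording(rep(1, fs), fs)
  expect_true(all(shannon_envelope(c2)$values == 0))
  expect_error(shannon_envelope(audio_recording(rnorm(10), 1000)),
               class = "hs_frame_too_long")
})

test_that("envelope is invariant to a global sign flip", {
  set.seed(7)
  rec <- audio_recording(runif(4000, -1, 1), 4000)
  flip <- audio_recording(-rec$samples, 4000)
  expect_equal(shannon_envelope(rec)$values, shannon_envelope(flip)$values,
               tolerance = 1e-14)
})

test_that("trimming crops to whole cycles and shifts the first S1 to zero", {
  cfg <- synthetic_pcg_config(heart_rate_bpm = 72, duration_s = 10,
                              cycle_jitter_pct = 0, snr_db = 30, seed = 5)
  g <- generate_pcg(cfg)
  fs <- g$recording$sample_rate
  lead <- 0.3
  set.seed(9)
  padded <- audio_recording(c(rnorm(lead * fs, sd = 0.01), g$recording$samples), fs)
  shifted <- as.data.frame(g$truth)
  shifted$start_s <- shifted$start_s + lead
  shifted$end_s <- shifted$end_s + lead
  seg <- cycle_segmentation(shifted)
  out <- trim_partial_cycles(padded, seg)
  expect_equal(min(out$segmentation$start_s), 0)
  # every retained duration preserved exactly
  expect_equal(out$segmentation$end_s - out$segmentation$start_s,
               seg$end_s - seg$start_s, tolerance = 1e-12)
  expect_equal(length(out$recording$samples),
               round(max(seg$end_s) * fs) - round(min(seg$start_s) * fs))

  # already starting at S1: audio unchanged up to edge cropping
  out2 <- trim_partial_cycles(g$recording, g$truth)
  expect_equal(min(out2$segmentation$start_s), 0)
  expect_equal(out2$segmentation$start_s, g$truth$start_s)

  one <- cycle_segmentation(as.data.frame(g$truth)[1:4, ])
  expect_error(trim_partial_cycles(g$recording, one),
               class = "hs_insufficient_cycles")
})
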