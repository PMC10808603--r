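test_that("shape statistics agree with the brute-force oracle to 1e-12", {
  set.seed(21)
  rec_fs <- 1000
  for (i in 1:20) {
    n <- sample(10:100, 1)
    x <- runif(n, -1, 1)
    rec <- audio_recording(x, rec_fs)
    iv <- segment_interval(0, n / rec_fs, "S1")
    got <- stat_features(rec, iv)
    want <- oracle_stats(x)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("frame dB levels agree with the brute-force oracle to 1e-12", {
  set.seed(22)
  fs <- 2000
  for (i in 1:10) {
    n <- sample(50:400, 1)
    x <- runif(n, -1, 1)
    rec <- audio_recording(x, fs)
    iv <- segment_interval(0, n / fs, "S2")
    got <- amplitude_features(rec, iv)
    want <- oracle_amplitude(x, fs)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("amplitude closed forms hold (0 dB, -6.02 dB, silence floor)", {
  fs <- 1000
  full <- audio_recording(rep(1, fs), fs)
  a1 <- amplitude_features(full, whole_interval(full))
  expect_equal(unlist(a1), c(maxdb = 0, mindb = 0, meandb = 0, middledb = 0))
  half <- audio_recording(rep(0.5, fs), fs)
  a2 <- amplitude_features(half, whole_interval(half))
  expect_equal(unname(unlist(a2)), rep(20 * log10(0.5), 4), tolerance = 1e-12)
  sil <- audio_recording(numeric(fs), fs)
  a3 <- amplitude_features(sil, whole_interval(sil))
  expect_equal(unname(unlist(a3)), rep(-120, 4))
  short <- amplitude_features(full, segment_interval(0, 0.005, "S1"))
  expect_true(attr(short, "single_frame"))
})

test_that("stat closed forms: alternating unit vector, constants, Gaussian kurtosis", {
  fs <- 1000
  alt <- audio_recording(c(1, -1, 1, -1), fs)
  st <- stat_features(alt, segment_interval(0, 4 / fs, "S1"))
  expect_equal(st[c("absomean", "STD", "RMS", "shapefactor", "impulsefactor",
                    "marginfactor", "peak2valley", "energy", "skew", "kurt")],
               list(absomean = 1, STD = 1, RMS = 1, shapefactor = 1,
                    impulsefactor = 1, marginfactor = 1, peak2valley = 2,
                    energy = 4, skew = 0, kurt = 1))

  const <- audio_recording(rep(0.4, 100), fs)
  stc <- stat_features(const, segment_interval(0, 0.1, "S1"))
  expect_equal(stc$shapefactor, 1)
  expect_equal(stc$impulsefactor, 1)
  expect_true(is.na(stc$skew) && is.na(stc$kurt))

  set.seed(23)
  g <- rnorm(1e5)
  rec <- audio_recording(g / max(abs(g)), fs)
  stg <- stat_features(rec, segment_interval(0, 100, "S1"))
  expect_equal(stg$kurt, 3, tolerance = 0.1 / 3)

  # zero-mean segments: STD equals RMS (population convention)
  z <- g[1:1000] - mean(g[1:1000])
  recz <- audio_recording(z / max(abs(z)), fs)
  stz <- stat_features(recz, segment_interval(0, 1, "S1"))
  expect_equal(stz$STD, stz$RMS, tolerance = 1e-14)
})

test_that("f0 features recover a pure tone and flag white noise unvoiced", {
  tone <- make_sine(100, 1, fs = 8000)
  iv <- whole_interval(tone)
  f0 <- f0_features(tone, iv)
  expect_equal(f0$mean_f0, 100, tolerance = 0.01)
  expect_lte(f0$f0variation, 1)
  expect_identical(f0$range_f0, f0$max_f0 - f0$min_f0)
  expect_equal(f0$median_f0, 100, tolerance = 0.01)

  set.seed(24)
  noise <- audio_recording(runif(8000, -1, 1), 8000)
  f0n <- f0_features(noise, whole_interval(noise))
  expect_true(all(is.na(unlist(f0n))))

  tiny <- segment_interval(0, 0.01, "S1")
  expect_error(f0_features(tone, tiny), class = "hs_interval_too_short")
})

test_that("quality features: tone jitter 0 and high HNR; noise HNR <= 0", {
  tone <- make_sine(100, 1, fs = 8000)
  q <- quality_features(tone, whole_interval(tone))
  expect_equal(q$jitter, 0, tolerance = 1e-6)
  expect_gte(q$HNR, 20)

  set.seed(25)
  noise <- audio_recording(runif(8000, -1, 1), 8000)
  qn <- quality_features(noise, whole_interval(noise))
  expect_lte(qn$HNR, 0)
})

test_that("harmonic-ratio block separates periodic from aperiodic segments", {
  tone <- make_sine(100, 1, fs = 8000)
  hr <- hr_ratio_features(tone, whole_interval(tone))
  expect_gte(hr$hr_max, 0.95)
  expect_true(all(unlist(hr) >= 0 & unlist(hr) <= 1))

  set.seed(26)
  noise <- audio_recording(runif(8000, -1, 1), 8000)
  hrn <- hr_ratio_features(noise, whole_interval(noise))
  expect_lte(hrn$hr_mean, 0.3)

  one <- hr_ratio_features(tone, segment_interval(0, 0.045, "S1"))
  expect_identical(one$hr_std, 0)
})

test_that("per-cycle duration table follows the label definitions", {
  rows <- data.frame(
    cycle = rep(1:2, each = 4),
    state = rep(c("S1", "SYSTOLE", "S2", "DIASTOLE"), 2),
    start_s = c(0, 0, 0.30, 0.30, 0.83, 0.83, 1.13, 1.13),
    end_s = c(0.12, 0.30, 0.42, 0.83, 0.95, 1.13, 1.25, 1.66))
  seg <- cycle_segmentation(rows)
  td <- time_domain_features(seg)
  expect_equal(td$s1, c(0.12, 0.12))
  expect_equal(td$systole, c(0.30, 0.30))
  expect_equal(td$diastole, c(0.53, 0.53))
  expect_equal(td$cycle_duration, c(0.83, 0.83))
  smry <- attr(td, "summary")
  expect_equal(unlist(smry[smry$statistic == "sd", -1]),
               c(s1 = 0, s2 = 0, systole = 0, diastole = 0, cycle_duration = 0))
  # 0.83 s cycles imply 72 bpm
  expect_identical(estimate_heart_rate(seg), 72L)
  empty <- cycle_segmentation(data.frame(cycle = integer(), state = character(),
                                         start_s = numeric(), end_s = numeric()))
  expect_error(time_domain_features(empty), class = "hs_degenerate_segmentation")
})

test_that("extract_all yields 4 rows per cycle and a per-state summary", {
  cfg <- synthetic_pcg_config(heart_rate_bpm = 72, duration_s = 10,
                              cycle_jitter_pct = 0, snr_db = 30, seed = 8)
  g <- generate_pcg(cfg)
  rec <- standardize(g$recording)
  keep <- g$truth$cycle <= 10
  seg <- cycle_segmentation(as.data.frame(g$truth)[keep, ])
  tab <- extract_all(rec, seg)
  expect_identical(nrow(tab), 40L)
  expect_identical(sort(unique(tab$state)), sort(c("S1", "systole", "S2", "diastole")))
  smry <- attr(tab, "summary")
  expect_identical(nrow(smry), 4L)

  # S1 inside systole: the systolic max-based features dominate
  s1max <- tab$maxdb[tab$state == "S1"]
  sysmax <- tab$maxdb[tab$state == "systole"]
  expect_true(all(sysmax >= s1max - 1e-9))
  # dB features are nonpositive on standardized input
  dbcols <- unlist(tab[, c("maxdb", "mindb", "meandb", "middledb")])
  expect_true(all(dbcols <= 1e-9, na.rm = TRUE))

  empty <- cycle_segmentation(data.frame(cycle = integer(), state = character(),
                                         start_s = numeric(), end_s = numeric()))
  tab0 <- extract_all(rec, empty)
  expect_identical(nrow(tab0), 0L)
  expect_true(all(c("cycle", "state", "duration_s", "maxdb", "hr_min") %in%
                    names(tab0)))
})
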