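test_that("the R-peak detector recovers generator ground truth", {
  rr <- generate_rr(60, 20, duration = 60.5, seed = 3)
  ecg <- generate_ecg(rr, fs = 256)
  peaks <- detect_r_peaks(ecg)
  expect_gte(length(peaks), 59)
  expect_lte(length(peaks), 62)

  # 5-minute recording: >= 99% of beats within one sample of the truth
  rr5 <- generate_rr(72, 40, duration = 300, seed = 5)
  ecg5 <- generate_ecg(rr5, fs = 256)
  det <- detect_r_peaks(ecg5)
  truth <- (attr(ecg5, "r_samples") - 1L) / 256
  err <- vapply(det, function(p) min(abs(truth - p)), numeric(1))
  expect_gte(mean(err <= 1 / 256 + 1e-9), 0.99)
  # sensitivity and PPV vs truth (match within 50 ms)
  matched <- vapply(truth, function(g) any(abs(det - g) < 0.05), logical(1))
  expect_gte(mean(matched), 0.99)                       # sensitivity
  expect_gte(mean(vapply(det, function(p) any(abs(truth - p) < 0.05),
                         logical(1))), 0.99)            # PPV

  # polarity inversion changes nothing
  det_inv <- detect_r_peaks(ecg_recording(-ecg5$samples, fs = 256))
  expect_equal(length(det_inv), length(det))

  expect_error(detect_r_peaks(ecg_recording(rep(0, 256), fs = 256)),
               class = "coldperf_validation_error")
})

test_that("interval cleaning gates, applies Malik's rule, and interpolates", {
  # out-of-range middle interval replaced by its neighbours' mean
  rr <- rr_series(cumsum(c(800, 250, 820)) / 1000, c(800, 250, 820))
  cl <- clean_rr(rr)
  expect_equal(cl$intervals, c(800, 810, 820))
  expect_equal(cl$interpolated, c(FALSE, TRUE, FALSE))
  expect_equal(attr(cl, "n_interpolated"), 1L)

  # in-range series with small successive changes is untouched
  x <- c(800, 820, 830, 825, 810)
  rr2 <- rr_series(cumsum(x) / 1000, x)
  expect_equal(clean_rr(rr2)$intervals, x)

  # Malik's rule: 1100 differs from the previous accepted 800 by 37.5%
  x3 <- c(800, 800, 1100, 800)
  cl3 <- clean_rr(rr_series(cumsum(x3) / 1000, x3))
  expect_equal(cl3$intervals, c(800, 800, 800, 800))
  expect_equal(which(cl3$interpolated), 3L)

  # idempotence
  cl3b <- clean_rr(cl3)
  expect_equal(cl3b$intervals, cl3$intervals)
  expect_equal(attr(cl3b, "n_interpolated"), 0L)

  # unusable segment: more than half invalid
  bad <- c(800, 100, 2000, 100, 2000)
  expect_error(clean_rr(rr_series(cumsum(bad) / 1000, bad)),
               class = "coldperf_validation_error")
})

test_that("HRV features match closed forms on constructed series", {
  # metronomic 1000 ms beats
  rr <- rr_series(cumsum(rep(1000, 70)) / 1000, rep(1000, 70))
  f <- hrv_feature_vector(rr, midpoint = NULL)
  expect_equal(f$hr, 60)
  expect_equal(f$rmssd, 0)
  expect_lt(f$hf, 1e-9)

  # alternating 800/850 ms: rmssd = 50, hr = 60000/825
  alt <- rep(c(800, 850), 40)
  rra <- rr_series(cumsum(alt) / 1000, alt)
  fa <- hrv_feature_vector(rra, midpoint = NULL)
  expect_equal(fa$rmssd, 50)
  expect_equal(fa$hr, 60000 / 825, tolerance = 1e-6)

  # fewer than 30 beats in a window is an error
  expect_error(hrv_feature_vector(rr, midpoint = 10, width = 20),
               class = "coldperf_validation_error")
})

test_that("HRV features obey shift and offset invariances", {
  rr <- generate_rr(75, 35, duration = 200, seed = 8)
  f1 <- hrv_feature_vector(rr, midpoint = 100)
  shifted <- rr_series(rr$beat_times + 5, rr$intervals)
  f2 <- hrv_feature_vector(shifted, midpoint = 105)
  expect_equal(f2$hr, f1$hr)
  expect_equal(f2$rmssd, f1$rmssd)

  plus <- rr_series(cumsum(rr$intervals + 100) / 1000, rr$intervals + 100)
  f3 <- hrv_feature_vector(plus, midpoint = NULL)
  f0 <- hrv_feature_vector(rr, midpoint = NULL)
  expect_equal(f3$rmssd, f0$rmssd, tolerance = 1e-9)
})

test_that("features recover the generator's parameters", {
  for (seed in 1:3) {
    hr0 <- c(62, 75, 88)[seed]
    rm0 <- c(25, 40, 55)[seed]
    rr <- generate_rr(hr0, rm0, duration = 300, seed = seed)
    f <- hrv_feature_vector(rr, midpoint = 150)
    expect_lt(abs(f$hr - hr0), 1)
    expect_lt(abs(f$rmssd - rm0) / rm0, 0.15)
  }
})
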