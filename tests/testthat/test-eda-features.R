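test_that("decomposition separates phasic and tonic components", {
  # constant input: all tonic, no phasic activity
  r <- generate_eda(6, 0, duration = 120, fs = 4, noise_sd = 0, seed = 1)
  d <- decompose_eda(r)
  expect_lt(max(abs(d$phasic)), 0.01)
  expect_equal(mean(d$tonic), 6, tolerance = 1e-3)

  # known SCRs: recovered phasic tracks the generating kernel sum
  ev <- data.frame(time_s = c(20, 40, 60, 80, 100), amplitude = 0.2)
  r2 <- generate_eda(6, 0.02, ev, duration = 120, fs = 4, noise_sd = 0, seed = 1)
  d2 <- quiet_decompose(r2)
  expect_gt(stats::cor(d2$phasic, attr(r2, "phasic_true")), 0.9)
  # residual power < 5% of (centered) input power on noiseless signals
  expect_lt(sum(d2$residual^2),
            0.05 * sum((r2$samples - mean(r2$samples))^2))
  expect_gt(min(d2$driver), -1e-9)
})

test_that("decomposition is positively homogeneous up to the sparsity term", {
  ev <- data.frame(time_s = c(25, 60, 95), amplitude = 0.15)
  r <- generate_eda(4, 0.01, ev, duration = 120, fs = 4, noise_sd = 0, seed = 1)
  d1 <- quiet_decompose(r)
  d2 <- quiet_decompose(eda_recording(r$samples * 2, fs = 4))
  expect_gt(stats::cor(d1$phasic, d2$phasic), 0.999)
  expect_equal(sum(d2$phasic) / sum(d1$phasic), 2, tolerance = 0.05)
  expect_equal(d2$tonic / d1$tonic, rep(2, length(d1$tonic)), tolerance = 0.01)
})

test_that("decomposition validates its inputs", {
  expect_error(decompose_eda(eda_recording(rep(5, 100), fs = 4)),
               ">= 60 s", class = "coldperf_validation_error")
})

test_that("TVSymp reconstructs the sympathetic band with unit gain", {
  fs <- 4
  t <- (0:(300 * fs - 1)) / fs
  tone <- function(f) eda_recording(pmax(5 + sin(2 * pi * f * t), 0), fs = fs)
  core <- function(tv) {
    n <- length(tv$amplitude)
    tv$amplitude[round(n * 0.2):round(n * 0.8)]
  }
  # unit-variance in-band tone -> envelope sqrt(2) within 5% away from edges
  tv <- compute_tvsymp(tone(0.16))
  expect_equal(mean(core(tv)), sqrt(2), tolerance = 0.05)
  expect_true(all(tv$amplitude >= 0))
  # out-of-band tone rejected
  tv2 <- compute_tvsymp(tone(0.5))
  expect_lt(mean(core(tv2)), 0.1)
  # constant input: zero amplitude everywhere
  tvz <- compute_tvsymp(eda_recording(rep(3, 600), fs = 4))
  expect_true(all(tvz$amplitude == 0))
  # invariant to adding a constant to the input
  shifted <- eda_recording(tone(0.16)$samples + 2, fs = fs)
  expect_equal(compute_tvsymp(shifted)$amplitude, tv$amplitude,
               tolerance = 1e-10)
  # too-short input rejected
  expect_error(compute_tvsymp(eda_recording(rep(3, 90), fs = 4)),
               class = "coldperf_validation_error")
})

test_that("window extraction follows the half-open sample convention", {
  rec <- eda_recording(seq_len(480) / 100, fs = 4)
  w <- extract_window(rec, midpoint = 90, width = 60)
  expect_length(w$samples, 240)
  # [60 s, 90 s) at 4 Hz -> 0-based samples [240, 480) -> 1-based 241:480
  expect_equal(w$samples, rec$samples[241:480])
  expect_error(extract_window(eda_recording(rep(1, 240), fs = 4), 20, 60,
                              task = "CDS"),
               "CDS", class = "coldperf_window_error")
})

test_that("SCR counting thresholds onset-to-peak amplitudes", {
  expect_equal(count_nsscr(rep(0, 240), 0.05, fs = 4), 0)

  r <- make_scr_recording(rep(0.08, 5))
  d <- quiet_decompose(r)
  ph <- extract_window(d$phasic, 90, 60, fs = 4)
  expect_equal(count_nsscr(ph, 0.05, fs = 4), 5)
  expect_equal(count_nsscr(ph, 0.01, fs = 4), 5)

  r2 <- make_scr_recording(c(0.03, 0.2, 0.03, 0.2, 0.03))
  d2 <- quiet_decompose(r2)
  ph2 <- extract_window(d2$phasic, 90, 60, fs = 4)
  expect_equal(count_nsscr(ph2, 0.05, fs = 4), 2)
  expect_equal(count_nsscr(ph2, 0.01, fs = 4), 5)
})

test_that("SCR counts are monotone non-increasing in the threshold", {
  set.seed(4)
  for (i in 1:5) {
    amps <- stats::runif(6, 0.01, 0.3)
    r <- make_scr_recording(amps, seed = i)
    ph <- quiet_decompose(r)$phasic
    counts <- vapply(c(0.005, 0.01, 0.05, 0.1, 0.2), function(th)
      count_nsscr(ph, th, fs = 4), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the EDA feature vector summarizes the task window", {
  # constant input: zero spreads and zero counts
  rc <- eda_recording(rep(6, 720), fs = 4)
  fv <- eda_feature_vector(rc, midpoint = 90)
  expect_equal(fv$pheda_sd, 0, tolerance = 1e-6)
  expect_equal(fv$toneda_sd, 0, tolerance = 1e-4)
  expect_equal(fv$nsscr_005 + fv$nsscr_001, 0)
  expect_equal(fv$toneda_mean, 6, tolerance = 1e-3)

  # doubling SCR amplitudes strictly increases the phasic mean
  f1 <- eda_feature_vector(make_scr_recording(rep(0.1, 5)), 90)
  f2 <- eda_feature_vector(make_scr_recording(rep(0.2, 5)), 90)
  expect_gt(f2$pheda_mean, f1$pheda_mean)

  # window bound violations are reported with the task name
  expect_error(eda_feature_vector(rc, midpoint = 5, task = "GNG"),
               "GNG", class = "coldperf_window_error")
})
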