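test_that("generate_eda builds tonic + kernel-convolved SCRs deterministically", {
  # zero-phasic case: constant tonic only
  r <- generate_eda(6, 0, duration = 60, fs = 4, noise_sd = 0, seed = 1)
  expect_equal(r$samples, rep(6, 240))

  # five events produce exactly five local maxima above half their height
  ev <- data.frame(time_s = c(20, 45, 70, 95, 120), amplitude = 0.1)
  r2 <- generate_eda(5, 0, ev, duration = 150, fs = 4, noise_sd = 0, seed = 1)
  ph <- r2$samples - 5
  n <- length(ph)
  is_max <- c(FALSE, ph[2:(n - 1)] > ph[1:(n - 2)] & ph[2:(n - 1)] >= ph[3:n], FALSE)
  expect_equal(sum(is_max & ph > 0.05), 5)

  # determinism under a fixed seed
  a <- generate_eda(5, 0.1, ev, 150, 4, noise_sd = 0.01, seed = 9)
  b <- generate_eda(5, 0.1, ev, 150, 4, noise_sd = 0.01, seed = 9)
  expect_identical(a$samples, b$samples)

  # event outside the recording is rejected
  expect_error(generate_eda(5, 0, data.frame(time_s = 200, amplitude = 0.1),
                            duration = 100, fs = 4),
               class = "coldperf_validation_error")
})

test_that("generate_rr hits its rate and variability targets", {
  # degenerate: no variability at all
  rr0 <- generate_rr(60, 0, hf_mod_amp = 0, duration = 120, seed = 1)
  expect_true(all(abs(rr0$intervals - 1000) < 1e-9))

  # cohort emulation targets: HR and RMSSD recovered downstream
  rr <- generate_rr(70.4, 47.1, duration = 300, seed = 2)
  f <- hrv_feature_vector(rr, midpoint = 150)
  expect_gt(f$hr, 69.4); expect_lt(f$hr, 71.4)
  expect_gt(f$rmssd, 40.0); expect_lt(f$rmssd, 54.2)

  # a pure sinusoidal modulation carries a^2/2 power in its band
  a <- 30
  rrh <- generate_rr(70, 0, hf_mod_freq = 0.25, hf_mod_amp = a,
                     duration = 300, seed = 1)
  fh <- hrv_feature_vector(rrh, midpoint = 150)
  expect_lt(abs(fh$hf - a^2 / 2) / (a^2 / 2), 0.2)

  # infeasible variability is rejected
  expect_error(generate_rr(180, 200, duration = 120),
               class = "coldperf_validation_error")
  expect_error(generate_rr(20, 10, duration = 120),
               class = "coldperf_validation_error")
})

test_that("generate_ecg places recoverable R peaks", {
  rr <- rr_series(cumsum(rep(1000, 10)) / 1000, rep(1000, 10))
  ecg <- generate_ecg(rr, fs = 256)
  peaks <- attr(ecg, "r_samples")
  expect_length(peaks, 11)
  expect_true(all(diff(peaks) == 256))

  # amplitude scaling leaves detected peak times unchanged
  rr5 <- generate_rr(72, 40, duration = 120, seed = 5)
  e1 <- generate_ecg(rr5, fs = 256, amplitude = 1)
  e2 <- ecg_recording(e1$samples * 2, fs = 256)
  expect_equal(detect_r_peaks(e1), detect_r_peaks(e2))

  expect_error(generate_ecg(rr5, fs = 64), class = "coldperf_validation_error")
})

test_that("generate_cohort reproduces the study design and its own truth", {
  cfg <- synthetic_config(seed = 42)
  coh <- generate_cohort(cfg)
  expect_length(coh$eda_recordings, 19)
  expect_named(coh$eda_recordings[[1]], c("normal", "cold"))
  # 19 subjects x 2 conditions x 5 sessions x 5 tasks
  expect_equal(nrow(coh$performance), 19 * 2 * 5 * 5)
  expect_equal(sort(unique(coh$schedules$task)),
               sort(c("CDS", "PRO", "GNG", "SPD", "SRT")))
  expect_equal(max(coh$schedules$session), 5)

  # every scheduled window lies inside its recording
  for (subj in c("S01", "S19")) {
    for (cond in c("normal", "cold")) {
      sch <- coh$schedules[coh$schedules$subject == subj &
                             coh$schedules$condition == cond, ]
      expect_true(all(sch$task_start_s >= 0))
      expect_true(all(sch$task_end_s <=
                        duration_s(coh$eda_recordings[[subj]][[cond]])))
      expect_true(all(sch$task_end_s <=
                        max(coh$rr_series[[subj]][[cond]]$beat_times)))
    }
  }

  # bit-identical regeneration under the same seed
  expect_identical(coh, generate_cohort(synthetic_config(seed = 42)))
})

test_that("labels recovered from the performance table match ground truth when noiseless", {
  cfg <- synthetic_config(n_subjects = 5, rt_noise_sd = 0, seed = 7)
  coh <- generate_cohort(cfg)
  lab <- label_cohort_performance(coh$performance)
  gt <- coh$ground_truth$deteriorated
  key <- function(d) paste(d$subject, d$task, d$session)
  m <- match(key(lab), key(gt))
  expect_false(anyNA(m))
  expect_equal(lab$label == "deteriorated", gt$deteriorated[m])
})

test_that("written cohorts round-trip through the io readers", {
  coh <- generate_cohort(synthetic_config(n_subjects = 2, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  eda_back <- read_e4_eda(file.path(dir, "S01_cold_eda.csv"))
  expect_equal(eda_back$samples, coh$eda_recordings$S01$cold$samples,
               tolerance = 1e-8)
  sched_back <- read_schedule(file.path(dir, "schedule.csv"))
  expect_equal(nrow(sched_back), nrow(coh$schedules))
  perf_back <- read_performance(file.path(dir, "performance.csv"))
  expect_equal(perf_back$rt_ms, coh$performance$rt_ms, tolerance = 1e-8)
})
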