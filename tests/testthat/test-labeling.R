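test_that("the deterioration threshold is the 2nd slowest baseline session", {
  expect_equal(deterioration_threshold(c(400, 420, 450, 480, 500))$threshold_rt, 480)
  expect_equal(deterioration_threshold(rep(500, 5))$threshold_rt, 500)
  expect_equal(deterioration_threshold(c(400, 410))$threshold_rt, 400)
  expect_error(deterioration_threshold(400), class = "coldperf_validation_error")
})

test_that("cold sessions are labeled by strict comparison to the threshold", {
  thr <- deterioration_threshold(c(400, 420, 450, 480, 500),
                                 subject_id = "S01", task = "GNG")
  expect_equal(label_sessions(c(470, 485, 500, 460, 490), thr),
               c("normal", "deteriorated", "deteriorated", "normal",
                 "deteriorated"))
  # a value exactly at the threshold stays normal
  expect_equal(label_sessions(480, thr), "normal")
  expect_equal(label_sessions(c(100, 200, 300), thr), rep("normal", 3))
  expect_error(label_sessions(500, thr, subject_id = "S02"),
               class = "coldperf_validation_error")
  expect_error(label_sessions(500, thr, task = "CDS"),
               class = "coldperf_validation_error")
})

test_that("increasing a cold reaction time never clears a deteriorated label", {
  set.seed(2)
  for (i in 1:50) {
    base <- stats::runif(5, 300, 700)
    thr <- deterioration_threshold(base)
    rt <- stats::runif(1, 300, 700)
    l1 <- label_sessions(rt, thr)
    l2 <- label_sessions(rt + stats::runif(1, 0, 200), thr)
    expect_false(l1 == "deteriorated" && l2 == "normal")
  }
})

test_that("under exchangeability the expected deteriorated fraction is 1/3", {
  # a fresh i.i.d. draw beats the 2nd largest of 5 exchangeable baselines
  # exactly when it ranks 1st or 2nd among all 6 values: probability 2/6
  set.seed(10)
  n <- 30000
  base <- matrix(stats::runif(n * 5), ncol = 5)
  cold <- stats::runif(n)
  det <- vapply(seq_len(n), function(i) {
    label_sessions(cold[i], deterioration_threshold(base[i, ])) ==
      "deteriorated"
  }, logical(1))
  expect_equal(mean(det), 1 / 3, tolerance = 0.03)
})

test_that("performance tables are labeled per subject and task, excluding SRT", {
  perf <- rbind(
    data.frame(subject = "S01", condition = "normal", session = 1:5,
               task = "CDS", rt_ms = c(400, 420, 450, 480, 500)),
    data.frame(subject = "S01", condition = "cold", session = 1:5,
               task = "CDS", rt_ms = c(470, 485, 500, 460, 490)),
    data.frame(subject = "S01", condition = "normal", session = 1:5,
               task = "SRT", rt_ms = 300),
    data.frame(subject = "S01", condition = "cold", session = 1:5,
               task = "SRT", rt_ms = 400))
  lab <- label_cohort_performance(perf)
  expect_false("SRT" %in% lab$task)
  expect_equal(lab$label[lab$task == "CDS"],
               c("normal", "deteriorated", "deteriorated", "normal",
                 "deteriorated"))
})
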