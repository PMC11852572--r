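test_that("skin and body temperature formulas evaluate exactly", {
  # convex combination: equal sites give the common value
  expect_equal(area_weighted_skin_temp(33, 33, 33), 33)
  expect_equal(area_weighted_skin_temp(34, 30, 32), 32.125)
  expect_equal(sum(coldperf:::skin_weights), 1)

  expect_equal(mean_body_temp(37, 37), 37)
  expect_equal(mean_body_temp(30, 37), 34.48)
})

test_that("both formulas are monotone convex combinations", {
  set.seed(1)
  for (i in 1:20) {
    s <- stats::runif(3, 25, 40)
    ts <- area_weighted_skin_temp(s[1], s[2], s[3])
    expect_gte(ts, min(s)); expect_lte(ts, max(s))
    # monotone in each site
    expect_gt(area_weighted_skin_temp(s[1] + 1, s[2], s[3]), ts)
    core <- stats::runif(1, 35, 39)
    mbt <- mean_body_temp(ts, core)
    expect_gte(mbt, min(ts, core)); expect_lte(mbt, max(ts, core))
  }
})

test_that("temperature inputs are validated and summarized per session", {
  expect_error(area_weighted_skin_temp(33, NA, 32),
               class = "coldperf_validation_error")
  expect_warning(area_weighted_skin_temp(50, 33, 33), "plausibility")

  temps <- data.frame(time_s = seq(0, 1800, by = 60),
                      t_forehead = 33, t_hand = 32, t_calf = 31.5,
                      t_core = 37)
  sched <- data.frame(subject = "S01", condition = "cold",
                      session = c(1, 1, 2), task = c("CDS", "PRO", "CDS"),
                      task_start_s = c(300, 450, 1200),
                      task_end_s = c(420, 540, 1320))
  s <- summarize_temperature(temps, sched)
  expect_equal(nrow(s), 2)
  expect_equal(s$t_skin, rep(area_weighted_skin_temp(33, 32, 31.5), 2))
  expect_equal(s$t_mbt, rep(mean_body_temp(s$t_skin[1], 37), 2))
})
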