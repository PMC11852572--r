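test_that("the pooled t-test behaves at its boundary cases", {
  x <- c(1, 2, 3, 4)
  r <- two_sample_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  a <- c(1.2, 3.4, 2.2, 4.1)
  b <- c(2.0, 2.8, 3.9, 5.0, 4.4)
  r1 <- two_sample_t(a, b)
  r2 <- two_sample_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$df, length(a) + length(b) - 2)

  expect_error(two_sample_t(1, c(1, 2)), class = "coldperf_validation_error")
  expect_error(two_sample_t(c(1, 1), c(2, 2)),
               class = "coldperf_validation_error")
})

test_that("pooled-SD Cohen's d has its analytic symmetries", {
  expect_equal(cohens_d(5, 1, 10, 5, 2, 12)$d, 0)
  d1 <- cohens_d(1.5, 0.6, 20, 2.1, 0.8, 25)
  # scale invariance
  d2 <- cohens_d(1.5 * 3, 0.6 * 3, 20, 2.1 * 3, 0.8 * 3, 25)
  expect_equal(d2$d, d1$d)
  # antisymmetry under group swap
  d3 <- cohens_d(2.1, 0.8, 25, 1.5, 0.6, 20)
  expect_equal(d3$d, -d1$d)
  # CI contains d and tightens with n
  expect_lte(d1$ci_low, d1$d); expect_gte(d1$ci_high, d1$d)
  d4 <- cohens_d(1.5, 0.6, 200, 2.1, 0.8, 250)
  expect_lt(d4$ci_high - d4$ci_low, d1$ci_high - d1$ci_low)
  expect_error(cohens_d(1, 0, 5, 1, 0, 5), class = "coldperf_validation_error")
})

test_that("effect sizes reproduce the published summary-statistic cells", {
  # NSSCR 0.01, code substitution: normal (1.72 +/- 2.91, n 36) vs
  # deteriorated (4.95 +/- 4.05, n 38)
  expect_equal(round(cohens_d(1.72, 2.91, 36, 4.95, 4.05, 38)$d, 2), 0.91)
  # heart rate, Go/No-go
  expect_equal(round(cohens_d(71.7, 8.4, 45, 77.9, 9.4, 44)$d, 2), 0.70)
  # heart rate, spatial discrimination
  expect_equal(round(cohens_d(71.4, 7.9, 37, 79.6, 10.0, 42)$d, 1), 0.9)
})

test_that("the comparison table covers every task x feature cell", {
  set.seed(3)
  n <- 40
  ft <- data.frame(subject = rep(sprintf("S%02d", 1:8), each = 5),
                   condition = "cold", session = rep(1:5, 8),
                   task = rep(c("CDS", "GNG"), each = 20))
  for (f in feature_names("Both")) ft[[f]] <- stats::rnorm(n)
  ft$hr <- ft$hr + 3 * (seq_len(n) %% 2)       # planted difference
  ft$label <- ifelse(seq_len(n) %% 2 == 1, "deteriorated", "normal")
  st <- feature_stats_table(ft)
  expect_equal(nrow(st), 2 * length(feature_names("Both")))
  expect_true(all(st$d_ci_low <= st$d & st$d <= st$d_ci_high))
  hr_rows <- st[st$feature == "hr", ]
  expect_true(all(hr_rows$d > 0))
})
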