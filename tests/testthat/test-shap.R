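test_that("attributions of a linear model match the closed form", {
  p <- make_separable_problem(n_sub = 12, n_seg = 8, seed = 3)
  m <- coldperf:::fit_model("LR", list(C = 1), p$X, p$y, seed = 1)
  fi <- feature_importance(m, p$X, p$X[1:10, ], n_perm = 50, seed = 2)
  beta <- m$fit$beta[-1]
  closed <- sweep(p$X[1:10, ], 2, colMeans(p$X), "-") %*% diag(beta)
  expect_lt(max(abs(fi$attributions - closed)) / max(abs(closed)), 0.1)
})

test_that("the planted informative features rank first", {
  p <- make_separable_problem(n_sub = 12, n_seg = 8, seed = 5)
  m <- coldperf:::fit_model("SVM", list(C = 1), p$X, p$y, seed = 1)
  fi <- feature_importance(m, p$X, p$X[1:15, ], n_perm = 40, seed = 3)
  expect_setequal(fi$ranking[1:2], c("f1", "f2"))
})

test_that("a duplicated irrelevant feature stays unimportant", {
  p <- make_separable_problem(n_sub = 12, n_seg = 8, seed = 7)
  X2 <- cbind(p$X, f6 = p$X[, 3])
  m <- coldperf:::fit_model("SVM", list(C = 1), X2, p$y, seed = 1)
  fi <- feature_importance(m, X2, X2[1:15, ], n_perm = 40, seed = 4)
  informative <- min(fi$importance[c("f1", "f2")])
  expect_lt(fi$importance["f3"], 0.2 * informative)
  expect_lt(fi$importance["f6"], 0.2 * informative)
})

test_that("an empty background is rejected and plain functions work", {
  f <- function(X) X[, 1] - 2 * X[, 2]
  X <- matrix(stats::rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(feature_importance(f, X[0, , drop = FALSE], X),
               class = "coldperf_validation_error")
  fi <- feature_importance(f, X, X[1:5, ], n_perm = 30, seed = 1)
  expect_equal(unname(fi$attributions[, "a"]),
               X[1:5, "a"] - mean(X[, "a"]), tolerance = 0.2)
})
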