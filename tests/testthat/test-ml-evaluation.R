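test_that("score metrics satisfy their identities", {
  expect_equal(geometric_mean_score(1, 1), 1)
  expect_equal(geometric_mean_score(0, 0.7), 0)
  expect_equal(geometric_mean_score(0.25, 1), 0.5)
  expect_error(geometric_mean_score(1.2, 0.5))

  expect_equal(accuracy_from_rates(1, 1, 40, 35), 1)
  expect_warning(accuracy_from_rates(0.51, 1, 7, 7), "not consistent")
})

test_that("LOSO folds partition the segments by subject", {
  ids <- rep(sprintf("S%02d", 1:19), times = 4)
  folds <- make_loso_folds(ids)
  expect_length(folds, 19)
  test_union <- sort(unname(unlist(lapply(folds, `[[`, "test"))))
  expect_equal(test_union, seq_along(ids))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_false(f$subject %in% ids[f$train])
  }
  expect_error(make_loso_folds(rep("S01", 5)),
               class = "coldperf_validation_error")
})

test_that("SVM-SMOTE balances classes with interpolated minority points", {
  set.seed(5)
  n <- 80
  p <- list(X = matrix(stats::rnorm(n * 4), ncol = 4),
            y = rep(c(0L, 1L), c(55, 25)),
            groups = rep(sprintf("P%02d", 1:10), each = 8))
  p$X[, 1] <- p$X[, 1] + 3 * p$y
  colnames(p$X) <- paste0("f", 1:4)
  bal <- balance_training(p$X, p$y, seed = 1, groups = p$groups)
  expect_equal(sum(bal$y == 1), sum(bal$y == 0))
  expect_equal(bal$X[!bal$synthetic, ], p$X)
  expect_equal(length(bal$groups), nrow(bal$X))

  # every synthetic point lies on a segment between two minority points
  minority <- as.integer(names(which.min(table(p$y))))
  Xm <- p$X[p$y == minority, , drop = FALSE]
  syn <- bal$X[bal$synthetic, , drop = FALSE]
  on_segment <- function(pt) {
    for (i in seq_len(nrow(Xm) - 1)) for (j in (i + 1):nrow(Xm)) {
      a <- Xm[i, ]; b <- Xm[j, ]
      ab <- b - a
      u <- sum((pt - a) * ab) / sum(ab^2)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((pt - (a + u * ab))^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_gte(nrow(syn), 5)
  expect_true(all(apply(syn[1:5, , drop = FALSE], 1, on_segment)))

  # already balanced input is returned unchanged
  yb <- rep(c(0, 1), 20)
  Xb <- matrix(stats::rnorm(80), ncol = 2)
  bal2 <- balance_training(Xb, yb, seed = 2)
  expect_equal(bal2$X, Xb)

  # degenerate minority falls back to duplication with a warning
  y1 <- c(rep(0, 10), 1)
  X1 <- matrix(stats::rnorm(22), ncol = 2)
  expect_warning(b3 <- balance_training(X1, y1, seed = 3), "duplication")
  expect_equal(sum(b3$y == 1), sum(b3$y == 0))
})

test_that("grid search selects by mean geometric-mean over subject groups", {
  p <- make_separable_problem(n_sub = 10, n_seg = 8, seed = 7)
  spec <- model_spec("SVM")
  tuned <- tune_hyperparameters(p$X, p$y, p$groups, spec, seed = 1)
  expect_length(tuned$grid_gm, nrow(spec$grid))
  expect_gt(tuned$mean_gm, 0.95)
  # separable: ties at the top resolve to the first grid entry
  top <- which(abs(tuned$grid_gm - max(tuned$grid_gm)) < 1e-12)
  expect_equal(tuned$params$C, spec$grid$C[top[1]])
  # determinism
  tuned2 <- tune_hyperparameters(p$X, p$y, p$groups, spec, seed = 1)
  expect_identical(tuned, tuned2)

  expect_error(tune_hyperparameters(p$X, p$y, rep("A", length(p$y)), spec),
               class = "coldperf_validation_error")
})

test_that("all four model families run through the LOSO protocol", {
  p <- make_separable_problem(n_sub = 8, n_seg = 6, seed = 11)
  df <- as.data.frame(p$X)
  for (fam in c("LR", "SVM", "RF", "MLP")) {
    r <- evaluate_loso(df, p$y, p$groups, spec = model_spec(fam),
                       seed = 2, tune = FALSE)
    expect_s3_class(r, "eval_result")
    expect_equal(sum(r$confusion), length(p$y))
    expect_equal(r$gm^2, r$sensitivity * r$specificity, tolerance = 1e-12)
    expect_gt(r$auroc, 0.9)  # separable by construction
  }
})

test_that("the LOSO protocol separates, nulls out, and never leaks", {
  p <- make_separable_problem(n_sub = 12, n_seg = 8, seed = 3)
  df <- as.data.frame(p$X)
  r <- evaluate_loso(df, p$y, p$groups, spec = model_spec("SVM"), seed = 5)
  expect_gte(r$gm, 0.95)
  expect_gte(r$auroc, 0.98)

  # permutation null: chance-level AUROC
  set.seed(11)
  yp <- sample(p$y)
  rp <- evaluate_loso(df, yp, p$groups, spec = model_spec("SVM"), seed = 5)
  expect_lt(abs(rp$auroc - 0.5), 0.1)

  # determinism of the full pipeline
  r2 <- evaluate_loso(df, p$y, p$groups, spec = model_spec("SVM"), seed = 5)
  expect_identical(r$scores, r2$scores)
  expect_identical(r$confusion, r2$confusion)

  # no leakage: per-fold scaler statistics recompute from training rows only
  for (s in names(r$per_fold)[1:3]) {
    info <- r$per_fold[[s]]
    bal <- balance_training(p$X[info$train, , drop = FALSE], p$y[info$train],
                            seed = coldperf:::derive_seed(5, s),
                            groups = p$groups[info$train])
    expect_equal(info$scaler$mean, colMeans(bal$X))
    expect_false(isTRUE(all.equal(info$scaler$mean, colMeans(p$X))))
  }
})

test_that("labels can arrive as normal/deteriorated strings", {
  p <- make_separable_problem(n_sub = 8, n_seg = 6, seed = 13)
  lab <- ifelse(p$y == 1, "deteriorated", "normal")
  r <- evaluate_loso(as.data.frame(p$X), lab, p$groups,
                     spec = model_spec("LR"), seed = 1, tune = FALSE)
  expect_equal(unname(r$confusion["TP"] + r$confusion["FN"]), sum(p$y == 1))
})
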