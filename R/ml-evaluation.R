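# Leave-one-subject-out (LOSO) evaluation protocol.
#
# Per fold: the held-out subject's segments form the test set; the
# remaining subjects are balanced with SVM-SMOTE, standardized with
# training statistics only (except for random forest), hyperparameters are
# tuned by exhaustive grid search with five-fold subject-group cross
# validation maximizing the geometric-mean score, the winning model is
# refit and scored on the test subject. Test predictions are pooled over
# folds for the confusion matrix and a single AUROC.

#' Geometric-mean score
#'
#' `sqrt(sensitivity * specificity)` — the balanced selection and
#' reporting statistic of the protocol.
#'
#' @param sensitivity,specificity rates in \[0, 1\].
#' @return the score in \[0, 1\].
#' @examples
#' geometric_mean_score(0.842, 0.806)  # 0.824
#' @export
geometric_mean_score <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sqrt(sensitivity * specificity)
}

#' Reconstruct accuracy from printed rates and class counts
#'
#' Recovers the pooled accuracy implied by a reported sensitivity and
#' specificity given the class sizes:
#' `(round(sens * n_pos) + round(spec * n_neg)) / (n_pos + n_neg)`.
#' Warns when a rate is not consistent with an integer count.
#'
#' @param sensitivity,specificity rates in \[0, 1\].
#' @param n_pos,n_neg class sizes (positives = deteriorated).
#' @return accuracy in \[0, 1\].
#' @examples
#' accuracy_from_rates(0.842, 0.806, 38, 36)  # 61/74
#' @export
accuracy_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, n_pos > 0, n_neg > 0)
  tp <- sensitivity * n_pos
  tn <- specificity * n_neg
  if (abs(tp - round(tp)) > 0.1 || abs(tn - round(tn)) > 0.1) {
    warning("rates are not consistent with integer counts at these class sizes")
  }
  (round(tp) + round(tn)) / (n_pos + n_neg)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: its segments are the test set, everything else
#' trains. Folds partition the data; a subject with no segments is skipped
#' with a warning.
#'
#' @param subject_ids vector of per-segment subject identifiers.
#' @return named list of folds, each `list(subject, train, test)` with
#'   integer row indices.
#' @export
make_loso_folds <- function(subject_ids) {
  subject_ids <- as.character(subject_ids)
  subjects <- sort(unique(subject_ids))
  if (length(subjects) < 2L) {
    stop_coldperf("LOSO requires >= 2 subjects", "coldperf_validation_error")
  }
  folds <- list()
  for (s in subjects) {
    test <- which(subject_ids == s)
    if (length(test) == 0L) {
      warning(sprintf("subject %s has no segments; skipped", s))
      next
    }
    folds[[s]] <- list(subject = s, train = which(subject_ids != s),
                       test = test)
  }
  folds
}

#' Balance a training set with SVM-SMOTE
#'
#' Oversamples the minority class to parity by interpolating between
#' minority points near the decision boundary and their minority
#' neighbours: a linear SVM is fit to the training data, its
#' minority-class support vectors seed synthetic points
#' `seed + u * (neighbour - seed)` with `u ~ U(0, 1)` and the neighbour
#' drawn among the seed's `k` nearest minority points — so every synthetic
#' point lies on a segment between two minority points. Falls back to
#' random duplication (with a warning) when the minority class has fewer
#' than 2 samples.
#'
#' @param X numeric matrix of features (training fold only).
#' @param y 0/1 labels.
#' @param seed RNG seed.
#' @param k number of minority neighbours.
#' @param groups optional per-row group (subject) labels; synthetic rows
#'   inherit the seed point's group.
#' @return list with balanced `X`, `y`, `groups` and logical `synthetic`
#'   marking generated rows.
#' @export
balance_training <- function(X, y, seed = 1, k = 5, groups = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop_coldperf("both classes must be present to balance",
                  "coldperf_validation_error")
  }
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == n0) {
    return(list(X = X, y = y, groups = groups,
                synthetic = rep(FALSE, length(y))))
  }
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n1 - n0)
  min_idx <- which(y == minority)
  if (length(min_idx) < 2L) {
    warning("minority class < 2 samples: falling back to random duplication")
    dup <- with_seed(seed,
                     min_idx[sample.int(length(min_idx), need, replace = TRUE)])
    return(list(X = rbind(X, X[dup, , drop = FALSE]),
                y = c(y, y[dup]),
                groups = if (is.null(groups)) NULL else c(groups, groups[dup]),
                synthetic = c(rep(FALSE, length(y)), rep(TRUE, need))))
  }
  # boundary seeds: minority support vectors of a linear SVM
  sv_seeds <- tryCatch({
    m <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = 1, scale = any(apply(X, 2, stats::sd) > 0))
    iv <- m$index[y[m$index] == minority]
    if (length(iv) == 0L) min_idx else iv
  }, error = function(e) min_idx)
  Xm <- X[min_idx, , drop = FALSE]
  kk <- min(k, length(min_idx) - 1L)
  new_rows <- matrix(NA_real_, nrow = need, ncol = ncol(X))
  new_groups <- rep(NA, need)
  with_seed(seed, {
    for (i in seq_len(need)) {
      s_idx <- sv_seeds[(i - 1L) %% length(sv_seeds) + 1L]
      s_pt <- X[s_idx, ]
      d2 <- colSums((t(Xm) - s_pt)^2)
      d2[min_idx == s_idx] <- Inf
      nb <- min_idx[order(d2)[seq_len(kk)]]
      j <- nb[sample.int(kk, 1L)]
      u <- stats::runif(1)
      new_rows[i, ] <- s_pt + u * (X[j, ] - s_pt)
      new_groups[i] <- if (is.null(groups)) NA else groups[s_idx]
    }
  })
  list(X = rbind(X, new_rows),
       y = c(y, rep(minority, need)),
       groups = if (is.null(groups)) NULL else c(groups, new_groups),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, need)))
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, sc) {
  sweep(sweep(as.matrix(X), 2, sc$mean, "-"), 2, sc$sd, "/")
}

confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == 1 & pred == 1), FN = sum(truth == 1 & pred == 0),
    FP = sum(truth == 0 & pred == 1), TN = sum(truth == 0 & pred == 0))
}

gm_from_confusion <- function(cm) {
  sens <- if (cm["TP"] + cm["FN"] > 0) cm["TP"] / (cm["TP"] + cm["FN"]) else NA
  spec <- if (cm["TN"] + cm["FP"] > 0) cm["TN"] / (cm["TN"] + cm["FP"]) else NA
  if (is.na(sens) || is.na(spec)) return(NA_real_)
  unname(geometric_mean_score(sens, spec))
}

#' Tune hyperparameters by grid search with subject-group cross-validation
#'
#' Subjects (sorted by id) are dealt round-robin into five groups; every
#' grid point is evaluated by training on four groups and scoring the
#' geometric mean on the fifth, for all five rotations. The winner has the
#' highest mean score; ties break toward the first grid row. Inner folds
#' missing a class contribute no score.
#'
#' @param train_X numeric feature matrix (already balanced/standardized).
#' @param train_y 0/1 labels.
#' @param train_groups per-row subject labels (>= 5 distinct subjects).
#' @param spec a [model_spec()].
#' @param seed RNG seed (model fitting).
#' @param n_groups number of tuning groups (5).
#' @return list with `params` (winning row of the grid as a list), `mean_gm`
#'   and the per-grid-point score vector `grid_gm`.
#' @export
tune_hyperparameters <- function(train_X, train_y, train_groups, spec,
                                 seed = 1, n_groups = 5) {
  stopifnot(inherits(spec, "model_spec"))
  subs <- sort(unique(as.character(train_groups)))
  if (length(subs) < n_groups) {
    stop_coldperf(sprintf("tuning requires >= %d distinct subjects", n_groups),
                  "coldperf_validation_error")
  }
  grp_of_sub <- stats::setNames((seq_along(subs) - 1L) %% n_groups + 1L, subs)
  grp <- grp_of_sub[as.character(train_groups)]
  grid <- spec$grid
  grid_gm <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    scores <- c()
    for (g in seq_len(n_groups)) {
      tr <- grp != g; te <- grp == g
      if (length(unique(train_y[tr])) < 2L ||
          length(unique(train_y[te])) < 2L) next
      m <- fit_model(spec$family, params, train_X[tr, , drop = FALSE],
                     train_y[tr], seed = derive_seed(seed, gi, g))
      sc <- predict_scores(m, train_X[te, , drop = FALSE])
      pred <- as.integer(sc > score_threshold(spec$family))
      scores <- c(scores, gm_from_confusion(confusion_counts(train_y[te], pred)))
    }
    grid_gm[gi] <- if (length(scores)) mean(scores, na.rm = TRUE) else NA_real_
  }
  best <- which.max(grid_gm)  # ties and NAs resolve to the first maximum
  list(params = as.list(grid[best, , drop = FALSE]), mean_gm = grid_gm[best],
       grid_gm = grid_gm)
}

#' Leave-one-subject-out evaluation of one model family on one feature set
#'
#' Runs the full protocol and pools test predictions over folds.
#'
#' @param features data.frame containing the feature columns, or a numeric
#'   matrix.
#' @param labels labels, either 0/1 or `"normal"`/`"deteriorated"`
#'   (deteriorated = positive class).
#' @param groups per-segment subject identifiers.
#' @param spec a [model_spec()] (or family name).
#' @param feature_set `"EDA"`, `"HRV"` or `"Both"` — selects the feature
#'   columns by name when `features` is a data.frame with the canonical
#'   schema; ignored for a bare matrix.
#' @param seed RNG seed controlling SMOTE and model fitting.
#' @param tune whether to grid-search hyperparameters per fold (default
#'   TRUE); `FALSE` uses the first grid row.
#' @return an object of class `eval_result`: confusion counts, sensitivity,
#'   specificity, accuracy, geometric-mean score, AUROC over pooled
#'   decision scores, per-fold winning hyperparameters, and per-fold
#'   leakage diagnostics (training row indices and scaler statistics).
#' @export
evaluate_loso <- function(features, labels, groups, spec = model_spec("SVM"),
                          feature_set = c("Both", "EDA", "HRV"), seed = 1,
                          tune = TRUE) {
  if (is.character(spec)) spec <- model_spec(spec)
  feature_set <- match.arg(feature_set)
  if (is.data.frame(features)) {
    cols <- intersect(feature_names(feature_set), names(features))
    if (length(cols) == 0L) cols <- names(features)[vapply(features, is.numeric, logical(1))]
    X <- as.matrix(features[cols])
  } else {
    X <- as.matrix(features)
    cols <- colnames(X)
  }
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(labels == "deteriorated")
  if (length(unique(y)) < 2L) {
    stop_coldperf("both classes must be present", "coldperf_validation_error")
  }
  groups <- as.character(groups)
  folds <- make_loso_folds(groups)
  scores <- rep(NA_real_, length(y))
  preds <- rep(NA_integer_, length(y))
  fold_info <- list()
  for (f in folds) {
    tr <- f$train; te <- f$test
    if (length(unique(y[tr])) < 2L) {
      warning(sprintf("fold %s: training data single-class; skipped", f$subject))
      next
    }
    fseed <- derive_seed(seed, f$subject)
    bal <- balance_training(X[tr, , drop = FALSE], y[tr], seed = fseed,
                            groups = groups[tr])
    sc <- NULL
    Xtr <- bal$X; Xte <- X[te, , drop = FALSE]
    if (spec$standardize) {
      sc <- standardize_fit(bal$X)
      Xtr <- standardize_apply(bal$X, sc)
      Xte <- standardize_apply(Xte, sc)
    }
    params <- if (tune) {
      tune_hyperparameters(Xtr, bal$y, bal$groups, spec, seed = fseed)$params
    } else as.list(spec$grid[1L, , drop = FALSE])
    m <- fit_model(spec$family, params, Xtr, bal$y, seed = fseed)
    s <- predict_scores(m, Xte)
    scores[te] <- s
    preds[te] <- as.integer(s > score_threshold(spec$family))
    fold_info[[f$subject]] <- list(subject = f$subject, params = params,
                                   train = tr, scaler = sc,
                                   n_synthetic = sum(bal$synthetic))
  }
  ok <- !is.na(preds)
  if (length(unique(y[ok])) < 2L) {
    stop_coldperf("a class is absent from the pooled truth: metrics undefined",
                  "coldperf_validation_error")
  }
  cm <- confusion_counts(y[ok], preds[ok])
  sens <- unname(cm["TP"] / (cm["TP"] + cm["FN"]))
  spc <- unname(cm["TN"] / (cm["TN"] + cm["FP"]))
  auroc <- as.numeric(pROC::auc(pROC::roc(response = y[ok],
                                          predictor = scores[ok],
                                          levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
  structure(list(
    family = spec$family, feature_set = feature_set, columns = cols,
    confusion = cm, sensitivity = sens, specificity = spc,
    accuracy = unname((cm["TP"] + cm["TN"]) / sum(cm)),
    gm = unname(geometric_mean_score(sens, spc)), auroc = auroc,
    scores = scores, predictions = preds, truth = y,
    per_fold = fold_info, seed = seed), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s on %s features\n", x$family, x$feature_set))
  cat(sprintf("  sens %.3f  spec %.3f  acc %.3f  gm %.3f  AUROC %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$gm, x$auroc))
  cat(sprintf("  confusion TP %d FN %d FP %d TN %d\n", x$confusion["TP"],
              x$confusion["FN"], x$confusion["FP"], x$confusion["TN"]))
  invisible(x)
}
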