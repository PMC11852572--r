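# Shapley-value feature attributions for fitted decision models.
#
# Sampling (permutation) estimator of interventional Shapley values on the
# model's decision score: for each explained point, random feature
# orderings are walked while absent features are filled from a sampled
# background row; the marginal change in the score when a feature enters
# is its contribution for that ordering. For a linear model every ordering
# yields exactly coef * (x - background), so the estimator reduces to the
# closed form coef * (x - mean(background)).

#' Shapley-value feature importance of a fitted model
#'
#' @param model a model returned by the evaluation protocol's fitting layer
#'   (internal class `coldperf_model`), or any function
#'   `f(X matrix) -> numeric scores`.
#' @param X_background matrix/data.frame of background points (defines the
#'   reference distribution; must be non-empty).
#' @param X_explain matrix/data.frame of points to explain.
#' @param n_perm number of sampled orderings per explained point.
#' @param n_background background rows averaged per ordering (sampled
#'   without replacement when the background is larger).
#' @param seed RNG seed.
#' @return a list of class `shap_result`: `attributions` (points x
#'   features), `importance` (mean absolute attribution per feature,
#'   sorted decreasing), `ranking` (feature names, most important first).
#' @export
feature_importance <- function(model, X_background, X_explain,
                               n_perm = 64, n_background = 20, seed = 1) {
  X_background <- as.matrix(X_background)
  X_explain <- as.matrix(X_explain)
  if (nrow(X_background) == 0L) {
    stop_coldperf("background set is empty", "coldperf_validation_error")
  }
  f <- if (is.function(model)) model else function(X) predict_scores(model, X)
  d <- ncol(X_explain)
  fn <- colnames(X_explain)
  if (is.null(fn)) fn <- paste0("x", seq_len(d))
  phi <- matrix(0, nrow = nrow(X_explain), ncol = d, dimnames = list(NULL, fn))
  nb <- min(n_background, nrow(X_background))
  with_seed(seed, {
    for (i in seq_len(nrow(X_explain))) {
      x <- X_explain[i, ]
      acc <- numeric(d)
      for (p in seq_len(n_perm)) {
        ord <- sample.int(d)
        bg <- X_background[sample.int(nrow(X_background), nb), , drop = FALSE]
        # walk the ordering for every background row in one batch:
        # block j holds the coalition of the first j-1 entered features
        Z <- matrix(NA_real_, nrow = (d + 1L) * nb, ncol = d)
        present <- rep(FALSE, d)
        for (j in seq_len(d + 1L)) {
          blk <- ((j - 1L) * nb + 1L):(j * nb)
          Z[blk, ] <- bg
          if (any(present)) {
            Z[blk, present] <- matrix(x[present], nrow = nb, ncol = sum(present),
                                      byrow = TRUE)
          }
          if (j <= d) present[ord[j]] <- TRUE
        }
        v <- colMeans(matrix(f(Z), nrow = nb))
        acc[ord] <- acc[ord] + diff(v)
      }
      phi[i, ] <- acc / n_perm
    }
  })
  imp <- sort(colMeans(abs(phi)), decreasing = TRUE)
  structure(list(attributions = phi, importance = imp,
                 ranking = names(imp)), class = "shap_result")
}

#' @export
print.shap_result <- function(x, ...) {
  cat("<shap_result> mean |attribution| per feature:\n")
  for (i in seq_along(x$importance)) {
    cat(sprintf("  %2d. %-12s %.4f\n", i, x$ranking[i], x$importance[i]))
  }
  invisible(x)
}
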