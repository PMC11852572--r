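# Two-sample comparisons of physiological features between normal- and
# deteriorated-performance segments: pooled-variance t-tests and Cohen's d
# with an approximate 95% confidence interval. The statistical unit is the
# one-minute segment.

#' Two-sided pooled-variance Student's t-test
#'
#' Thin wrapper around `stats::t.test(var.equal = TRUE)` returning the
#' statistic and p-value.
#'
#' @param group_a,group_b numeric vectors with >= 2 values each.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_coldperf("each group needs >= 2 values", "coldperf_validation_error")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, p = 1,
                                                    df = length(group_a) + length(group_b) - 2))
    stop_coldperf("zero pooled variance with unequal means",
                  "coldperf_validation_error")
  }
  ht <- stats::t.test(group_b, group_a, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Cohen's d with pooled standard deviation from group summaries
#'
#' `d = (mean2 - mean1) / s_pooled` with
#' `s_pooled^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`.
#' Group 1 is the normal-performance group, group 2 the deteriorated
#' group, so positive d means the feature is elevated under deterioration.
#' The 95% CI uses the large-sample standard error
#' `SE(d) = sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2-2)))` with normal
#' quantiles.
#'
#' @param mean1,sd1,n1 summary of the normal group.
#' @param mean2,sd2,n2 summary of the deteriorated group.
#' @return list of class `effect_size`: `d`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @examples
#' cohens_d(1.72, 2.91, 36, 4.95, 4.05, 38)$d  # ~0.91
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2 || sd1 < 0 || sd2 < 0) {
    stop_coldperf("need n >= 2 per group and non-negative SDs",
                  "coldperf_validation_error")
  }
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    stop_coldperf("pooled standard deviation is zero", "coldperf_validation_error")
  }
  d <- (mean2 - mean1) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  structure(list(d = d, ci_low = d - stats::qnorm(0.975) * se,
                 ci_high = d + stats::qnorm(0.975) * se, n1 = n1, n2 = n2),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.2f (95%% CI %.2f to %.2f), n = %d vs %d\n",
              x$d, x$ci_low, x$ci_high, x$n1, x$n2))
  invisible(x)
}

#' Feature-by-feature comparison table
#'
#' For each task and each feature column, compares normal vs deteriorated
#' segments: group means and SDs, pooled t-test p-value and Cohen's d with
#' its 95% CI.
#'
#' @param features labeled feature table (see [read_feature_table()]).
#' @return data.frame with one row per task x feature.
#' @export
feature_stats_table <- function(features) {
  fn <- feature_names("Both")
  need <- c("task", "label", fn)
  if (!all(need %in% names(features))) {
    stop_coldperf("feature table lacks required columns", "coldperf_schema_error")
  }
  rows <- list()
  for (task in unique(features$task)) {
    sub <- features[features$task == task, , drop = FALSE]
    g1 <- sub[sub$label == "normal", , drop = FALSE]
    g2 <- sub[sub$label == "deteriorated", , drop = FALSE]
    if (nrow(g1) < 2L || nrow(g2) < 2L) next
    for (f in fn) {
      tt <- tryCatch(two_sample_t(g1[[f]], g2[[f]]),
                     coldperf_validation_error = function(e) list(t = NA, p = NA))
      es <- tryCatch(cohens_d(mean(g1[[f]]), stats::sd(g1[[f]]), nrow(g1),
                              mean(g2[[f]]), stats::sd(g2[[f]]), nrow(g2)),
                     coldperf_validation_error = function(e)
                       list(d = NA, ci_low = NA, ci_high = NA))
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, feature = f,
        mean_normal = mean(g1[[f]]), sd_normal = stats::sd(g1[[f]]),
        n_normal = nrow(g1),
        mean_det = mean(g2[[f]]), sd_det = stats::sd(g2[[f]]),
        n_det = nrow(g2),
        p = tt$p, d = es$d, d_ci_low = es$ci_low, d_ci_high = es$ci_high)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
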