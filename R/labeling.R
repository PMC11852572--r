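# Performance-deterioration labeling.
#
# Each subject's normal-condition sessions define an individual threshold:
# the 2nd-slowest baseline reaction time for that task, i.e. the empirical
# 80th percentile of five baseline sessions. A cold-condition session whose
# reaction-time summary is strictly slower than the threshold is labeled
# "deteriorated"; labels are defined for cold sessions only, since the
# normal condition is consumed by the threshold.

#' Per-subject, per-task deterioration threshold
#'
#' The threshold is the 2nd largest baseline session reaction time. With
#' the canonical five baseline sessions this is the value whose empirical
#' exceedance fraction within the baseline is 1/5 (an "80th percentile" in
#' the plotting-position sense). Note that a fresh exchangeable draw
#' exceeds this finite-sample threshold with probability 1/3, not 1/5 —
#' see the methods vignette.
#'
#' @param baseline_rts numeric vector of baseline (normal-condition)
#'   session reaction times, ms; at least 2 values (canonically 5).
#' @param subject_id,task identifiers carried along for mismatch checks.
#' @return a list of class `deterioration_threshold` with `threshold_rt`,
#'   `n_baseline_sessions`, `subject_id`, `task`.
#' @examples
#' deterioration_threshold(c(400, 420, 450, 480, 500))$threshold_rt  # 480
#' @export
deterioration_threshold <- function(baseline_rts, subject_id = NA_character_,
                                    task = NA_character_) {
  baseline_rts <- as.numeric(baseline_rts)
  if (length(baseline_rts) < 2L || any(!is.finite(baseline_rts))) {
    stop_coldperf("need >= 2 finite baseline reaction times",
                  "coldperf_validation_error")
  }
  thr <- sort(baseline_rts, decreasing = TRUE)[2L]
  structure(list(threshold_rt = thr,
                 n_baseline_sessions = length(baseline_rts),
                 subject_id = subject_id, task = task),
            class = "deterioration_threshold")
}

#' Label cold-condition sessions against a deterioration threshold
#'
#' A session is `"deteriorated"` iff its reaction time is strictly greater
#' than the threshold ("slower than" the 2nd-slowest baseline); a value
#' exactly at the threshold is `"normal"`.
#'
#' @param cold_rts numeric vector of cold-condition session reaction
#'   times, ms.
#' @param thr a [deterioration_threshold()].
#' @param subject_id,task optional identifiers; if both the threshold and
#'   the call carry identifiers they must match.
#' @return character vector of labels, `"normal"` or `"deteriorated"`.
#' @export
label_sessions <- function(cold_rts, thr, subject_id = NULL, task = NULL) {
  stopifnot(inherits(thr, "deterioration_threshold"))
  if (!is.null(subject_id) && !is.na(thr$subject_id) &&
      !identical(as.character(subject_id), as.character(thr$subject_id))) {
    stop_coldperf(sprintf("threshold belongs to subject %s, not %s",
                          thr$subject_id, subject_id),
                  "coldperf_validation_error")
  }
  if (!is.null(task) && !is.na(thr$task) &&
      !identical(as.character(task), as.character(thr$task))) {
    stop_coldperf(sprintf("threshold belongs to task %s, not %s",
                          thr$task, task), "coldperf_validation_error")
  }
  ifelse(as.numeric(cold_rts) > thr$threshold_rt, "deteriorated", "normal")
}

#' Label every cold session in a performance table
#'
#' Applies [deterioration_threshold()] per subject x task to the
#' normal-condition rows and labels the cold-condition rows.
#'
#' @param performance data.frame with columns `subject`, `condition`,
#'   `session`, `task`, `rt_ms` (see [read_performance()]).
#' @param exclude_tasks tasks dropped from labeling (default `"SRT"`,
#'   which showed no deterioration and is excluded from analysis).
#' @return the cold-condition rows with an added `label` column.
#' @export
label_cohort_performance <- function(performance, exclude_tasks = "SRT") {
  need <- c("subject", "condition", "session", "task", "rt_ms")
  if (!all(need %in% names(performance))) {
    stop_coldperf("performance table lacks required columns",
                  "coldperf_schema_error")
  }
  perf <- performance[!performance$task %in% exclude_tasks, , drop = FALSE]
  out <- list()
  for (subj in unique(perf$subject)) {
    for (task in unique(perf$task[perf$subject == subj])) {
      base <- perf$rt_ms[perf$subject == subj & perf$task == task &
                           perf$condition == "normal"]
      cold <- perf[perf$subject == subj & perf$task == task &
                     perf$condition == "cold", , drop = FALSE]
      if (length(base) < 2L || nrow(cold) == 0L) next
      thr <- deterioration_threshold(base, subject_id = subj, task = task)
      cold$label <- label_sessions(cold$rt_ms, thr,
                                   subject_id = subj, task = task)
      out[[length(out) + 1L]] <- cold
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
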