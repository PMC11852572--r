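# End-to-end orchestration: simulate or ingest recordings, extract the
# per-segment feature table, label cold sessions, compute the comparison
# statistics, and run the LOSO evaluation grid — all driven by one config.

#' Extract the feature table for one recording pair
#'
#' Computes the 8 EDA + 3 HRV features for every scheduled task segment
#' (one-minute window centered on the task midpoint).
#'
#' @param eda an [eda_recording()].
#' @param rr an [rr_series()].
#' @param schedule data.frame of session records for this recording.
#' @param exclude_tasks tasks to skip (default `"SRT"`).
#' @return data.frame with identifier and feature columns (no label yet).
#' @export
extract_segment_features <- function(eda, rr, schedule,
                                     exclude_tasks = "SRT") {
  sched <- schedule[!schedule$task %in% exclude_tasks, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sched))) {
    mid <- (sched$task_start_s[i] + sched$task_end_s[i]) / 2
    ef <- eda_feature_vector(eda, mid, task = sched$task[i])
    hf <- hrv_feature_vector(rr, mid, task = sched$task[i])
    rows[[i]] <- cbind(sched[i, c("subject", "condition", "session", "task")],
                       ef, hf)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the feature table for a whole cohort
#'
#' @param cohort a [generate_cohort()] result (or an equivalent list built
#'   from files).
#' @param conditions conditions to process (default `"cold"`, the labeled
#'   condition).
#' @param exclude_tasks tasks to skip (default `"SRT"`).
#' @param progress print one line per recording.
#' @return unlabeled feature table.
#' @export
extract_cohort_features <- function(cohort, conditions = "cold",
                                    exclude_tasks = "SRT",
                                    progress = FALSE) {
  rows <- list()
  for (subj in names(cohort$eda_recordings)) {
    for (cond in intersect(conditions, names(cohort$eda_recordings[[subj]]))) {
      if (progress) message(sprintf("features: %s %s", subj, cond))
      sched <- cohort$schedules[cohort$schedules$subject == subj &
                                  cohort$schedules$condition == cond, ,
                                drop = FALSE]
      rows[[length(rows) + 1L]] <- extract_segment_features(
        cohort$eda_recordings[[subj]][[cond]],
        cohort$rr_series[[subj]][[cond]], sched,
        exclude_tasks = exclude_tasks)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach deterioration labels to a feature table
#'
#' @param features unlabeled feature table (cold-condition rows).
#' @param performance performance table covering both conditions.
#' @param exclude_tasks tasks never labeled (default `"SRT"`).
#' @return feature table with a `label` column, restricted to cold rows
#'   with a defined label.
#' @export
label_feature_table <- function(features, performance, exclude_tasks = "SRT") {
  labeled <- label_cohort_performance(performance, exclude_tasks)
  key <- function(df) paste(df$subject, df$session, df$task)
  m <- match(key(features[features$condition == "cold", , drop = FALSE]),
             key(labeled))
  out <- features[features$condition == "cold", , drop = FALSE]
  out$label <- labeled$label[m]
  out <- out[!is.na(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read the
#'   formats written by [write_cohort()] from `input_dir`).
#' @param input_dir directory of input files (files mode).
#' @param out_dir output directory for all artifacts.
#' @param tasks tasks to evaluate (SRT is never evaluated).
#' @param feature_sets subset of `c("EDA", "HRV", "Both")`.
#' @param models subset of `c("LR", "SVM", "RF", "MLP")`.
#' @param seed integer seed propagated to every stochastic stage.
#' @param tune per-fold hyperparameter tuning (disable for quick runs).
#' @param synthetic a [synthetic_config()] (synthetic mode); its seed is
#'   overridden by `seed`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), input_dir = NULL,
                       out_dir = "coldperf-out",
                       tasks = c("CDS", "PRO", "GNG", "SPD"),
                       feature_sets = c("EDA", "HRV", "Both"),
                       models = c("LR", "SVM", "RF", "MLP"),
                       seed = 1, tune = TRUE, synthetic = NULL) {
  mode <- match.arg(mode)
  tasks <- setdiff(tasks, "SRT")  # SRT never enters evaluation
  stopifnot(all(feature_sets %in% c("EDA", "HRV", "Both")),
            all(models %in% c("LR", "SVM", "RF", "MLP")))
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  synthetic$seed <- seed
  structure(list(mode = mode, input_dir = input_dir, out_dir = out_dir,
                 tasks = tasks, feature_sets = feature_sets, models = models,
                 seed = seed, tune = tune, synthetic = synthetic),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `synthetic`
#' block overrides [synthetic_config()] defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    syn <- do.call(synthetic_config, y$synthetic)
  }
  run_config(mode = y$mode %||% "synthetic", input_dir = y$input_dir,
             out_dir = y$out_dir %||% "coldperf-out",
             tasks = y$tasks %||% c("CDS", "PRO", "GNG", "SPD"),
             feature_sets = y$feature_sets %||% c("EDA", "HRV", "Both"),
             models = y$models %||% c("LR", "SVM", "RF", "MLP"),
             seed = y$seed %||% 1, tune = y$tune %||% TRUE, synthetic = syn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_cohort_files <- function(dir) {
  sched <- read_schedule(file.path(dir, "schedule.csv"))
  perf <- read_performance(file.path(dir, "performance.csv"))
  eda <- list(); rr <- list()
  for (subj in unique(sched$subject)) {
    eda[[subj]] <- list(); rr[[subj]] <- list()
    for (cond in unique(sched$condition[sched$subject == subj])) {
      ep <- file.path(dir, sprintf("%s_%s_eda.csv", subj, cond))
      rp <- file.path(dir, sprintf("%s_%s_rr.csv", subj, cond))
      for (p in c(ep, rp)) {
        if (!file.exists(p)) {
          stop_coldperf(sprintf(
            "missing recording for subject %s condition %s: '%s'",
            subj, cond, p), "coldperf_format_error")
        }
      }
      eda[[subj]][[cond]] <- read_e4_eda(ep)
      rr[[subj]][[cond]] <- read_rr(rp)
    }
  }
  list(eda_recordings = eda, rr_series = rr, schedules = sched,
       performance = perf)
}

#' Run the full pipeline
#'
#' Stages: simulate (or ingest), feature extraction, labeling, comparison
#' statistics, LOSO evaluation over every task x feature set x model, and
#' a manifest with seeds, versions and artifact checksums. Intermediate
#' artifacts are always written; the feature table is the interchange
#' point between the signal and evaluation halves.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @param progress print stage progress.
#' @return list with `features`, `labeled`, `stats`, `evaluations`,
#'   `manifest` (also written to `out_dir`).
#' @export
run_pipeline <- function(config, progress = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("simulate", {
    if (config$mode == "synthetic") {
      generate_cohort(config$synthetic)
    } else {
      read_cohort_files(config$input_dir)
    }
  })
  feats <- stage("features", {
    f <- extract_cohort_features(cohort, conditions = "cold",
                                 progress = progress)
    f[f$task %in% config$tasks, , drop = FALSE]
  })
  labeled <- stage("label", {
    lf <- label_feature_table(feats, cohort$performance)
    write_feature_table(lf, file.path(out, "feature_table.csv"))
    lf
  })
  stats_tab <- stage("stats", {
    s <- feature_stats_table(labeled)
    utils::write.csv(s, file.path(out, "feature_stats.csv"), row.names = FALSE)
    s
  })
  evals <- stage("evaluate", {
    res <- list()
    for (task in config$tasks) {
      sub <- labeled[labeled$task == task, , drop = FALSE]
      if (length(unique(sub$label)) < 2L) next
      for (fset in config$feature_sets) {
        for (fam in config$models) {
          if (progress) message(sprintf("evaluate: %s %s %s", task, fset, fam))
          r <- evaluate_loso(sub, sub$label, sub$subject,
                             spec = model_spec(fam), feature_set = fset,
                             seed = config$seed, tune = config$tune)
          key <- sprintf("%s_%s_%s", task, fset, fam)
          res[[key]] <- r
          jsonlite::write_json(list(
            task = task, feature_set = fset, family = fam,
            confusion = as.list(r$confusion), sensitivity = r$sensitivity,
            specificity = r$specificity, accuracy = r$accuracy, gm = r$gm,
            auroc = r$auroc, seed = r$seed,
            per_fold_params = lapply(r$per_fold, `[[`, "params")),
            file.path(out, sprintf("eval_%s.json", key)), auto_unbox = TRUE,
            digits = NA)
        }
      }
    }
    res
  })
  manifest <- stage("manifest", {
    files <- list.files(out, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    m <- list(package = "coldperf",
              version = as.character(utils::packageVersion("coldperf")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = config$seed, mode = config$mode,
              tasks = config$tasks, feature_sets = config$feature_sets,
              models = config$models,
              checksums = as.list(tools::md5sum(sort(files))))
    jsonlite::write_json(m, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })
  invisible(list(features = feats, labeled = labeled, stats = stats_tab,
                 evaluations = evals, manifest = manifest))
}
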