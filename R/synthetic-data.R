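# Synthetic cohort generator.
#
# Emulates the study design the pipeline targets: 19 subjects, each measured
# on a normal (23 degC) and a cold (10 degC) day, five sessions of a
# five-task cognitive battery repeated every 30 min, wrist EDA at 4 Hz,
# chest ECG at 256 Hz, per-session reaction-time summaries and skin/core
# temperature traces. Every stochastic element is recorded as ground truth
# so downstream feature extraction, labeling and evaluation can be verified
# against known parameters.

# Bateman (bi-exponential) skin-conductance-response kernel, normalized to
# unit peak so that an event "amplitude" is the peak height in uS.
bateman_kernel <- function(fs, tau_r = 0.75, tau_d = 2.0, t_max = 40) {
  t <- seq(0, t_max, by = 1 / fs)
  k <- exp(-t / tau_d) - exp(-t / tau_r)
  k / max(k)
}

#' Generate a synthetic EDA recording
#'
#' Signal model: a tonic ramp (`tonic_level` plus `drift_slope` per minute)
#' plus sparse skin-conductance responses — unit-impulse events convolved
#' with a Bateman bi-exponential kernel (rise 0.75 s, decay 2 s, unit peak)
#' — plus white Gaussian noise.
#'
#' @param tonic_level baseline skin conductance, µS.
#' @param drift_slope tonic drift, µS per minute.
#' @param scr_events data.frame with columns `time_s`, `amplitude` (µS peak
#'   height); may have zero rows.
#' @param duration recording length, seconds.
#' @param fs sampling rate, Hz.
#' @param noise_sd Gaussian noise SD, µS.
#' @param seed RNG seed.
#' @return an [eda_recording()] with attributes `scr_events` (the ground
#'   truth) and `tonic_true`, `phasic_true` (noiseless components).
#' @examples
#' r <- generate_eda(6, 0, data.frame(time_s = 30, amplitude = 0.2),
#'                   duration = 60, fs = 4, noise_sd = 0, seed = 1)
#' @export
generate_eda <- function(tonic_level, drift_slope = 0,
                         scr_events = data.frame(time_s = numeric(),
                                                 amplitude = numeric()),
                         duration = 60, fs = 4, noise_sd = 0, seed = 1) {
  stopifnot(fs > 0, duration > 0)
  if (nrow(scr_events) > 0L) {
    if (any(scr_events$amplitude < 0)) {
      stop_coldperf("SCR amplitudes must be non-negative", "coldperf_validation_error")
    }
    if (any(scr_events$time_s < 0 | scr_events$time_s > duration)) {
      stop_coldperf("SCR event time outside [0, duration]", "coldperf_validation_error")
    }
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  tonic <- tonic_level + drift_slope * t / 60
  driver <- numeric(n)
  if (nrow(scr_events) > 0L) {
    idx <- pmin(n, floor(scr_events$time_s * fs) + 1L)
    for (i in seq_along(idx)) driver[idx[i]] <- driver[idx[i]] + scr_events$amplitude[i]
  }
  kern <- bateman_kernel(fs)
  phasic <- stats::convolve(driver, rev(kern), type = "open")[seq_len(n)]
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, sd = noise_sd))
  } else numeric(n)
  x <- pmax(0, tonic + phasic + noise)
  rec <- eda_recording(x, fs = fs, start_time = 0)
  attr(rec, "scr_events") <- scr_events
  attr(rec, "tonic_true") <- tonic
  attr(rec, "phasic_true") <- phasic
  rec
}

#' Generate a synthetic R-R interval series
#'
#' Inter-beat intervals are a constant base (60000 / `hr_mean`) plus a
#' sinusoidal high-frequency modulation plus white jitter whose variance is
#' calibrated over three fixed iterations so the empirical RMSSD lands on
#' `rmssd_target`.
#'
#' @param hr_mean mean heart rate, bpm (30-200).
#' @param rmssd_target target RMSSD, ms (0 for a metronomic series).
#' @param hf_mod_freq modulation frequency, Hz (respiratory band).
#' @param hf_mod_amp modulation amplitude, ms.
#' @param duration series length, seconds (> 60).
#' @param seed RNG seed.
#' @return an [rr_series()] with attribute `params` echoing the generating
#'   parameters.
#' @export
generate_rr <- function(hr_mean, rmssd_target = 0, hf_mod_freq = 0.25,
                        hf_mod_amp = 0, duration = 120, seed = 1) {
  if (hr_mean < 30 || hr_mean > 200) {
    stop_coldperf("hr_mean must lie in [30, 200] bpm", "coldperf_validation_error")
  }
  if (duration <= 60) {
    stop_coldperf("duration must exceed 60 s", "coldperf_validation_error")
  }
  base <- 60000 / hr_mean
  if (hf_mod_amp + 4 * rmssd_target >= base) {
    stop_coldperf("rmssd_target/hf_mod_amp infeasible: intervals would reach 0",
                  "coldperf_validation_error")
  }
  n <- ceiling(duration * 1000 / base) + 2L
  t_approx <- (seq_len(n) - 1L) * base / 1000
  mod <- hf_mod_amp * sin(2 * pi * hf_mod_freq * t_approx)
  msd_mod <- mean(diff(mod)^2)
  sig2 <- max(0, (rmssd_target^2 - msd_mod) / 2)
  intervals <- NULL
  with_seed(seed, {
    for (iter in 1:3) {
      eps <- if (sig2 > 0) stats::rnorm(n, sd = sqrt(sig2)) else numeric(n)
      eps <- eps - mean(eps)          # keep the mean rate on target
      intervals <- base + mod + eps
      emp <- sqrt(mean(diff(intervals)^2))
      if (rmssd_target > 0 && emp > 0) {
        sig2 <- max(0, sig2 + (rmssd_target^2 - emp^2) / 2)
      }
    }
  })
  intervals <- pmax(intervals, 1)
  beat_times <- cumsum(intervals) / 1000
  keep <- beat_times <= duration + base / 1000
  rr <- rr_series(beat_times[keep], intervals[keep])
  attr(rr, "params") <- list(hr_mean = hr_mean, rmssd_target = rmssd_target,
                             hf_mod_freq = hf_mod_freq, hf_mod_amp = hf_mod_amp)
  rr
}

#' Synthesize an ECG trace from an R-R series
#'
#' Places one template beat — a dominant Gaussian R spike with a small
#' S-wave dip — at every beat time (including the beat opening the first
#' interval). Not a morphologically complete ECG; it exists to exercise the
#' R-peak detector against known peak positions.
#'
#' @param rr an [rr_series()].
#' @param fs sampling rate, Hz (>= 128).
#' @param amplitude R-wave amplitude, mV.
#' @return an [ecg_recording()] with attribute `r_samples`, the ground-truth
#'   R-peak sample indices (1-based).
#' @export
generate_ecg <- function(rr, fs = 256, amplitude = 1) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 128) {
    stop_coldperf("fs must be >= 128 Hz", "coldperf_validation_error")
  }
  if (length(rr$intervals) == 0L) {
    stop_coldperf("empty R-R series", "coldperf_validation_error")
  }
  first_beat <- rr$beat_times[1L] - rr$intervals[1L] / 1000
  peak_times <- c(first_beat, rr$beat_times) - first_beat
  n <- round((max(peak_times) + 0.3) * fs)
  x <- numeric(n)
  # R spike: Gaussian, sigma 9 ms; S dip: shifted Gaussian, 25% depth
  half <- round(0.06 * fs)
  tt <- (-half:half) / fs
  template <- amplitude * (exp(-tt^2 / (2 * 0.009^2)) -
                             0.25 * exp(-(tt - 0.025)^2 / (2 * 0.012^2)))
  r_samples <- round(peak_times * fs) + 1L
  for (p in r_samples) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    x[lo:hi] <- x[lo:hi] + template[(lo - p + half + 1L):(hi - p + half + 1L)]
  }
  rec <- ecg_recording(x, fs = fs, start_time = 0)
  attr(rec, "r_samples") <- r_samples
  rec
}

# ---- cohort configuration ---------------------------------------------------

#' Configuration for a synthetic cohort
#'
#' Defaults encode the emulated study conditions: 19 subjects, normal and
#' cold exposure days, five sessions repeated every 30 min, the five-task
#' battery (CDS 2, PRO 1.5, GNG 2.5, SPD 3, SRT 1.5 minutes), EDA at 4 Hz
#' and ECG at 256 Hz. Cold exposure attenuates electrodermal activity
#' (lower SCR rate and amplitude) while raising heart rate, and a latent
#' per-session "strain" couples reaction-time slowing with sympathetic
#' activation so deteriorated sessions carry a physiological signature.
#'
#' @param n_subjects number of subjects.
#' @param conditions the two condition labels.
#' @param n_sessions sessions per condition.
#' @param tasks named numeric vector of task durations in minutes.
#' @param eda_fs,ecg_fs sampling rates, Hz.
#' @param scr_rate named (per condition) SCR rate, events per minute.
#' @param scr_amp_range named list (per condition) of c(min, max) SCR peak
#'   amplitudes, µS.
#' @param tonic_level_range c(min, max) tonic skin conductance, µS.
#' @param tonic_drift_range c(min, max) tonic drift, µS/min.
#' @param eda_noise_sd EDA measurement noise SD, µS.
#' @param hr_mean_by_condition named mean heart rate, bpm.
#' @param hr_subject_sd between-subject HR SD, bpm.
#' @param hr_strain_gain extra bpm at maximal session strain (cold only).
#' @param rmssd_target_by_condition named RMSSD target, ms.
#' @param hf_mod_freq high-frequency (respiratory) modulation, Hz.
#' @param hf_mod_amp modulation amplitude, ms.
#' @param rt_base_range c(min, max) of subject x task baseline reaction
#'   time, ms.
#' @param rt_session_sd SD of the per-session shift of the true mean, ms.
#' @param rt_cold_effect maximal cold-induced slowing, ms (scaled by the
#'   session strain).
#' @param rt_noise_sd lognormal measurement noise SD of the session
#'   reaction-time summary, ms (0 gives the noiseless means).
#' @param scr_strain_gain relative SCR-rate elevation at maximal strain.
#' @param seed integer RNG seed; a fixed seed yields a bit-identical cohort.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 19,
                             conditions = c("normal", "cold"),
                             n_sessions = 5,
                             tasks = c(CDS = 2, PRO = 1.5, GNG = 2.5,
                                       SPD = 3, SRT = 1.5),
                             eda_fs = 4,
                             ecg_fs = 256,
                             scr_rate = c(normal = 3, cold = 1.5),
                             scr_amp_range = list(normal = c(0.05, 0.4),
                                                  cold = c(0.02, 0.15)),
                             tonic_level_range = c(2, 12),
                             tonic_drift_range = c(-0.05, 0.05),
                             eda_noise_sd = 0.003,
                             hr_mean_by_condition = c(normal = 70, cold = 75),
                             hr_subject_sd = 3,
                             hr_strain_gain = 10,
                             rmssd_target_by_condition = c(normal = 47, cold = 44),
                             hf_mod_freq = 0.25,
                             hf_mod_amp = 36,
                             rt_base_range = c(400, 1200),
                             rt_session_sd = 25,
                             rt_cold_effect = 120,
                             rt_noise_sd = 30,
                             scr_strain_gain = 1,
                             seed = 1234) {
  cfg <- list(n_subjects = n_subjects, conditions = conditions,
              n_sessions = n_sessions, tasks = tasks, eda_fs = eda_fs,
              ecg_fs = ecg_fs, scr_rate = scr_rate,
              scr_amp_range = scr_amp_range,
              tonic_level_range = tonic_level_range,
              tonic_drift_range = tonic_drift_range,
              eda_noise_sd = eda_noise_sd,
              hr_mean_by_condition = hr_mean_by_condition,
              hr_subject_sd = hr_subject_sd, hr_strain_gain = hr_strain_gain,
              rmssd_target_by_condition = rmssd_target_by_condition,
              hf_mod_freq = hf_mod_freq, hf_mod_amp = hf_mod_amp,
              rt_base_range = rt_base_range, rt_session_sd = rt_session_sd,
              rt_cold_effect = rt_cold_effect, rt_noise_sd = rt_noise_sd,
              scr_strain_gain = scr_strain_gain, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$conditions) != 2L ||
      !setequal(cfg$conditions, c("normal", "cold"))) {
    stop_coldperf("conditions must be exactly {normal, cold}",
                  "coldperf_validation_error")
  }
  pos <- c(cfg$n_subjects, cfg$n_sessions, cfg$tasks, cfg$eda_fs, cfg$ecg_fs,
           cfg$scr_rate, cfg$hf_mod_freq)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop_coldperf("all counts, durations and rates must be strictly positive",
                  "coldperf_validation_error")
  }
  if (is.null(names(cfg$tasks)) || any(!names(cfg$tasks) %in% valid_tasks())) {
    stop_coldperf("tasks must be a named vector of known task labels",
                  "coldperf_validation_error")
  }
  if (length(cfg$seed) != 1L || !is.finite(cfg$seed)) {
    stop_coldperf("seed must be a single integer", "coldperf_validation_error")
  }
  invisible(cfg)
}

# Session/task timeline shared by all subjects: 5 min baseline, then one
# session every 30 min; tasks run back-to-back with 30 s gaps.
cohort_timeline <- function(cfg) {
  session_start <- (5 + (seq_len(cfg$n_sessions) - 1) * 30) * 60
  rows <- list()
  for (s in seq_len(cfg$n_sessions)) {
    t0 <- session_start[s]
    for (task in names(cfg$tasks)) {
      dur <- cfg$tasks[[task]] * 60
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, task = task, task_start_s = t0, task_end_s = t0 + dur)
      t0 <- t0 + dur + 30
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "duration_s") <- (5 + cfg$n_sessions * 30) * 60 - 15 * 60
  out
}

#' Generate a full synthetic cohort
#'
#' Produces EDA recordings, R-R series, schedules, a reaction-time table
#' and temperature traces for every subject x condition, together with the
#' ground truth (SCR events, per-session HR/RMSSD parameters, noiseless
#' reaction-time means and the deteriorated-session flags computed from
#' those noiseless means with the baseline-percentile rule).
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_cohort` with elements
#'   `eda_recordings`, `rr_series` (nested lists indexed by subject id then
#'   condition), `schedules`, `performance`, `temperatures` and
#'   `ground_truth`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  cfg <- config
  timeline <- cohort_timeline(cfg)
  duration <- attr(timeline, "duration_s")
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  session_block_start <- c(0, (5 + (seq_len(cfg$n_sessions) - 1) * 30) * 60)
  session_block_end <- c(session_block_start[-1L], duration)

  eda_recordings <- list()
  rr_list <- list()
  schedules <- list()
  perf_rows <- list()
  temp_list <- list()
  gt_scr <- list()
  gt_hr <- list()
  gt_rt <- list()

  for (si in seq_along(subjects)) {
    subj <- subjects[si]
    eda_recordings[[subj]] <- list()
    rr_list[[subj]] <- list()
    temp_list[[subj]] <- list()
    # subject-level traits
    hr_offset <- with_seed(derive_seed(cfg$seed, si, "traits"), {
      stats::rnorm(1, sd = cfg$hr_subject_sd)
    })
    rt_base <- with_seed(derive_seed(cfg$seed, si, "rtbase"), {
      stats::setNames(stats::runif(length(cfg$tasks), cfg$rt_base_range[1],
                                   cfg$rt_base_range[2]), names(cfg$tasks))
    })
    for (cond in cfg$conditions) {
      # latent per-session strain in [0, 1]; drives RT slowing and
      # sympathetic activation in the cold condition only
      strain <- with_seed(derive_seed(cfg$seed, si, cond, "strain"), {
        stats::runif(cfg$n_sessions)
      })
      eff_strain <- if (cond == "cold") strain else rep(0, cfg$n_sessions)

      # --- reaction times -----------------------------------------------
      sess_shift <- with_seed(derive_seed(cfg$seed, si, cond, "rtsess"), {
        matrix(stats::rnorm(cfg$n_sessions * length(cfg$tasks),
                            sd = cfg$rt_session_sd),
               nrow = cfg$n_sessions)
      })
      for (ti in seq_along(cfg$tasks)) {
        task <- names(cfg$tasks)[ti]
        true_mean <- rt_base[[task]] + sess_shift[, ti] +
          cfg$rt_cold_effect * eff_strain
        rt_obs <- if (cfg$rt_noise_sd > 0) {
          with_seed(derive_seed(cfg$seed, si, cond, ti, "rtnoise"), {
            sdlog <- sqrt(log(1 + (cfg$rt_noise_sd / true_mean)^2))
            stats::rlnorm(cfg$n_sessions,
                          meanlog = log(true_mean) - sdlog^2 / 2,
                          sdlog = sdlog)
          })
        } else true_mean
        perf_rows[[length(perf_rows) + 1L]] <- data.frame(
          subject = subj, condition = cond,
          session = seq_len(cfg$n_sessions), task = task, rt_ms = rt_obs)
        gt_rt[[length(gt_rt) + 1L]] <- data.frame(
          subject = subj, condition = cond,
          session = seq_len(cfg$n_sessions), task = task,
          rt_true_mean = true_mean)
      }

      # --- EDA ----------------------------------------------------------
      lv <- with_seed(derive_seed(cfg$seed, si, cond, "tonic"), {
        c(stats::runif(1, cfg$tonic_level_range[1], cfg$tonic_level_range[2]),
          stats::runif(1, cfg$tonic_drift_range[1], cfg$tonic_drift_range[2]))
      })
      amp_rng <- cfg$scr_amp_range[[cond]]
      events <- with_seed(derive_seed(cfg$seed, si, cond, "scr"), {
        ev <- list()
        for (b in seq_along(session_block_start)) {
          blk_strain <- if (b == 1L) 0 else eff_strain[b - 1L]
          rate <- cfg$scr_rate[[cond]] * (1 + cfg$scr_strain_gain * blk_strain)
          blk_min <- (session_block_end[b] - session_block_start[b]) / 60
          k <- stats::rpois(1, rate * blk_min)
          if (k > 0) {
            ev[[length(ev) + 1L]] <- data.frame(
              time_s = sort(stats::runif(k, session_block_start[b],
                                         session_block_end[b])),
              amplitude = stats::runif(k, amp_rng[1], amp_rng[2]) *
                (1 + 0.5 * blk_strain))
          }
        }
        if (length(ev)) do.call(rbind, ev) else
          data.frame(time_s = numeric(), amplitude = numeric())
      })
      eda_recordings[[subj]][[cond]] <- generate_eda(
        tonic_level = lv[1], drift_slope = lv[2], scr_events = events,
        duration = duration, fs = cfg$eda_fs, noise_sd = cfg$eda_noise_sd,
        seed = derive_seed(cfg$seed, si, cond, "edanoise"))
      if (nrow(events)) {
        gt_scr[[length(gt_scr) + 1L]] <- cbind(
          data.frame(subject = subj, condition = cond), events)
      }

      # --- R-R intervals ------------------------------------------------
      segs <- list()
      t_off <- 0
      for (b in seq_along(session_block_start)) {
        blk_strain <- if (b == 1L) 0 else eff_strain[b - 1L]
        hr_b <- cfg$hr_mean_by_condition[[cond]] + hr_offset +
          cfg$hr_strain_gain * blk_strain
        blk_dur <- session_block_end[b] - session_block_start[b]
        seg <- generate_rr(hr_mean = hr_b,
                           rmssd_target = cfg$rmssd_target_by_condition[[cond]],
                           hf_mod_freq = cfg$hf_mod_freq,
                           hf_mod_amp = cfg$hf_mod_amp,
                           duration = blk_dur,
                           seed = derive_seed(cfg$seed, si, cond, b, "rr"))
        segs[[b]] <- list(t = seg$beat_times + session_block_start[b],
                          rr = seg$intervals)
        if (b > 1L) {
          gt_hr[[length(gt_hr) + 1L]] <- data.frame(
            subject = subj, condition = cond, session = b - 1L,
            hr_bpm = hr_b, rmssd_ms = cfg$rmssd_target_by_condition[[cond]])
        }
      }
      bt <- unlist(lapply(segs, `[[`, "t"))
      iv <- unlist(lapply(segs, `[[`, "rr"))
      ord <- order(bt)
      bt <- bt[ord]; iv <- iv[ord]
      keep <- c(TRUE, diff(bt) > 0.2)  # drop overlaps at block joins
      rr_list[[subj]][[cond]] <- rr_series(bt[keep], iv[keep])

      # --- temperatures -------------------------------------------------
      tmin <- seq(0, duration, by = 60)
      temp_list[[subj]][[cond]] <- with_seed(
        derive_seed(cfg$seed, si, cond, "temp"), {
          frac <- tmin / max(tmin)
          if (cond == "cold") {
            data.frame(time_s = tmin,
                       t_forehead = 33.5 - 3.0 * frac + stats::rnorm(length(tmin), sd = 0.1),
                       t_hand = 32.5 - 9.0 * frac + stats::rnorm(length(tmin), sd = 0.15),
                       t_calf = 32.0 - 6.0 * frac + stats::rnorm(length(tmin), sd = 0.15),
                       t_core = 37.0 - 0.4 * frac + stats::rnorm(length(tmin), sd = 0.05))
          } else {
            data.frame(time_s = tmin,
                       t_forehead = 33.8 + stats::rnorm(length(tmin), sd = 0.1),
                       t_hand = 33.0 + stats::rnorm(length(tmin), sd = 0.15),
                       t_calf = 32.3 + stats::rnorm(length(tmin), sd = 0.15),
                       t_core = 37.0 + stats::rnorm(length(tmin), sd = 0.05))
          }
        })

      schedules[[length(schedules) + 1L]] <- data.frame(
        subject = subj, condition = cond, session = timeline$session,
        task = timeline$task, task_start_s = timeline$task_start_s,
        task_end_s = timeline$task_end_s)
    }
  }

  performance <- do.call(rbind, perf_rows)
  rt_truth <- do.call(rbind, gt_rt)

  # deteriorated flags from the noiseless means, baseline-percentile rule
  det_rows <- list()
  for (subj in subjects) {
    for (task in names(cfg$tasks)) {
      base <- rt_truth$rt_true_mean[rt_truth$subject == subj &
                                      rt_truth$condition == "normal" &
                                      rt_truth$task == task]
      cold_idx <- rt_truth$subject == subj & rt_truth$condition == "cold" &
        rt_truth$task == task
      thr <- deterioration_threshold(base)
      det_rows[[length(det_rows) + 1L]] <- data.frame(
        subject = subj, task = task,
        session = rt_truth$session[cold_idx],
        rt_true_mean = rt_truth$rt_true_mean[cold_idx],
        threshold = thr$threshold_rt,
        deteriorated = rt_truth$rt_true_mean[cold_idx] > thr$threshold_rt)
    }
  }

  structure(list(
    config = cfg,
    eda_recordings = eda_recordings,
    rr_series = rr_list,
    schedules = do.call(rbind, schedules),
    performance = performance,
    temperatures = temp_list,
    ground_truth = list(
      scr_events = if (length(gt_scr)) do.call(rbind, gt_scr) else NULL,
      hr_sessions = do.call(rbind, gt_hr),
      rt_true = rt_truth,
      deteriorated = do.call(rbind, det_rows))
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x %d conditions, %d sessions, tasks: %s\n",
              x$config$n_subjects, length(x$config$conditions),
              x$config$n_sessions, paste(names(x$config$tasks), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk in the pipeline's file formats
#'
#' One EDA CSV (E4 dialect) and one R-R CSV per subject x condition, plus a
#' single schedule CSV, performance CSV and per-recording temperature CSVs,
#' so that a round trip through the readers reproduces the cohort.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in names(cohort$eda_recordings)) {
    for (cond in names(cohort$eda_recordings[[subj]])) {
      write_e4_eda(cohort$eda_recordings[[subj]][[cond]],
                   file.path(dir, sprintf("%s_%s_eda.csv", subj, cond)))
      write_rr(cohort$rr_series[[subj]][[cond]],
               file.path(dir, sprintf("%s_%s_rr.csv", subj, cond)))
      write_temperature(cohort$temperatures[[subj]][[cond]],
                        file.path(dir, sprintf("%s_%s_temp.csv", subj, cond)))
    }
  }
  write_schedule(cohort$schedules, file.path(dir, "schedule.csv"))
  write_performance(cohort$performance, file.path(dir, "performance.csv"))
  invisible(dir)
}
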