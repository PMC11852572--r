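# Skin and body temperature summaries.
#
# Area-weighted skin temperature uses ISO-9886-derived coefficients for the
# three measured sites (forehead, back of hand, calf), rescaled to sum to
# one; mean body temperature follows Burton's two-compartment formula.

skin_weights <- c(forehead = 0.21875, hand = 0.15625, calf = 0.625)

#' Area-weighted skin temperature
#'
#' `0.21875 * T_forehead + 0.15625 * T_hand + 0.625 * T_calf`; the weights
#' sum to exactly 1, so the result is a convex combination of the sites.
#' Values outside a 20-45 degC plausibility band trigger a warning.
#'
#' @param t_forehead,t_hand,t_calf site temperatures, degC (vectorized).
#' @return skin temperature, degC.
#' @examples
#' area_weighted_skin_temp(34, 30, 32)  # 32.125
#' @export
area_weighted_skin_temp <- function(t_forehead, t_hand, t_calf) {
  vals <- cbind(t_forehead, t_hand, t_calf)
  if (any(is.na(vals))) {
    stop_coldperf("all three skin sites must be present", "coldperf_validation_error")
  }
  if (any(vals < 20 | vals > 45)) {
    warning("skin temperature outside the 20-45 degC plausibility band")
  }
  drop(vals %*% skin_weights)
}

#' Burton mean body temperature
#'
#' `0.36 * t_skin + 0.64 * t_core`; a convex combination, hence always
#' between the two inputs.
#'
#' @param t_skin area-weighted skin temperature, degC.
#' @param t_core core temperature, degC.
#' @return mean body temperature, degC.
#' @examples
#' mean_body_temp(30, 37)  # 34.48
#' @export
mean_body_temp <- function(t_skin, t_core) {
  if (any(is.na(t_skin)) || any(is.na(t_core))) {
    stop_coldperf("both skin and core temperatures must be present",
                  "coldperf_validation_error")
  }
  0.36 * t_skin + 0.64 * t_core
}

#' Per-session temperature summary
#'
#' Means of skin, core and mean body temperature over each session window.
#'
#' @param temps data.frame as from [read_temperature()].
#' @param schedule data.frame of session records for one recording (see
#'   [read_schedule()]); session bounds are the min/max task times.
#' @return data.frame with one row per session: `session`, `t_skin`,
#'   `t_core`, `t_mbt`.
#' @export
summarize_temperature <- function(temps, schedule) {
  t_skin <- area_weighted_skin_temp(temps$t_forehead, temps$t_hand, temps$t_calf)
  t_mbt <- mean_body_temp(t_skin, temps$t_core)
  out <- lapply(sort(unique(schedule$session)), function(s) {
    lo <- min(schedule$task_start_s[schedule$session == s])
    hi <- max(schedule$task_end_s[schedule$session == s])
    sel <- temps$time_s >= lo & temps$time_s <= hi
    data.frame(session = s, t_skin = mean(t_skin[sel]),
               t_core = mean(temps$t_core[sel]), t_mbt = mean(t_mbt[sel]))
  })
  do.call(rbind, out)
}
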