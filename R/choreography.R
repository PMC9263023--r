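#' Build the experiment schedule
#'
#' Constructs the standard injury-and-resuscitation timeline: a 30% estimated
#' blood volume (EBV, 60 mL/kg) controlled hemorrhage over the first 30 min;
#' complete aortic balloon occlusion from T30 to T60; a calcium gluconate
#' infusion at T45 over 20 min (a scheduled no-op with respect to
#' hemodynamics, logged only); autologous transfusion back to 95% of EBV
#' starting at T55 over 18 min; a programmed linear balloon wean from T60
#' over 15 min; and a 255-min closed-loop critical-care phase from T75 to
#' T330.
#'
#' @param weight_kg subject weight in kg.
#' @param ebv_ml_per_kg estimated blood volume per kg (60 mL/kg).
#' @return a data.frame of class `experiment_schedule` with columns
#'   `action`, `start_s`, `end_s`, `volume_ml`, `rate_ml_min` and attribute
#'   `weight_kg`.
#' @export
#' @examples
#' sch <- build_schedule(70)
#' subset(sch, action == "hemorrhage")$volume_ml  # 1260 mL
build_schedule <- function(weight_kg, ebv_ml_per_kg = 60) {
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || !is.finite(weight_kg) ||
      weight_kg <= 0)
    stop("weight_kg must be a single positive number")
  ebv <- ebv_ml_per_kg * weight_kg
  hem_vol <- 0.30 * ebv
  tx_vol <- (0.95 - 0.70) * ebv
  sch <- data.frame(
    action = c("hemorrhage", "occlude", "calcium", "transfuse",
               "wean_balloon", "critical_care"),
    start_s = c(0, 1800, 2700, 3300, 3600, 4500),
    end_s = c(1800, 3600, 3900, 4380, 4500, 19800),
    volume_ml = c(hem_vol, NA, NA, tx_vol, NA, NA),
    rate_ml_min = c(hem_vol / 30, NA, NA, tx_vol / 18, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(sch, "weight_kg") <- weight_kg
  attr(sch, "ebv_ml") <- ebv
  class(sch) <- c("experiment_schedule", "data.frame")
  validate_schedule(sch)
  sch
}

# Reject overlapping use of the same actuator (volume pump, balloon, drug
# channel).  The transfusion deliberately overlaps the balloon wean; they
# use different actuators.
validate_schedule <- function(sch) {
  actuator <- c(hemorrhage = "volume_pump", transfuse = "volume_pump",
                occlude = "balloon", wean_balloon = "balloon",
                calcium = "drug_pump", critical_care = "controller")
  for (a in unique(actuator)) {
    rows <- sch[actuator[sch$action] == a, , drop = FALSE]
    if (nrow(rows) < 2) next
    rows <- rows[order(rows$start_s), ]
    if (any(rows$start_s[-1] < rows$end_s[-nrow(rows)]))
      stop("schedule conflict: overlapping actions on actuator '", a, "'")
  }
  invisible(sch)
}

# Aortic occlusion fraction at time t: full occlusion T30-T60, linear wean
# to zero over the following 15 min.
occlusion_at <- function(t, sch) {
  occ <- sch[sch$action == "occlude", ]
  wean <- sch[sch$action == "wean_balloon", ]
  ifelse(t >= occ$start_s & t < occ$end_s, 1,
         ifelse(t >= wean$start_s & t < wean$end_s,
                1 - (t - wean$start_s) / (wean$end_s - wean$start_s), 0))
}

# Reperfusion-injury exposure: zero while the balloon protects the proximal
# circulation, ramping in with the wean and complete thereafter.
injury_drive_at <- function(t, sch) {
  wean <- sch[sch$action == "wean_balloon", ]
  ifelse(t < wean$start_s, 0,
         ifelse(t < wean$end_s, (t - wean$start_s) / (wean$end_s - wean$start_s), 1))
}

#' Run a full choreographed experiment
#'
#' Executes the injury timeline of [build_schedule()] against the synthetic
#' patient and, during the critical-care window, runs the closed-loop
#' controller at its 60-s decision cadence on trailing 1-min averages of the
#' simulated vitals.  No decisions are taken while a bolus is infusing, and
#' after any bolus the next decision waits for the 60-s assessment window to
#' close.  Outside the critical-care window the controller is silent.
#'
#' @param params a [patient_params()].
#' @param config a [ctrl_config()] with matching `weight_kg`.
#' @param schedule an [build_schedule()] schedule (defaults to one built from
#'   `params$weight_kg`).
#' @param seed integer seed for the run's noise stream (`NULL` leaves the
#'   RNG state untouched).
#' @param controller logical; `FALSE` runs the untreated arm (baseline
#'   norepinephrine only, no boluses).
#' @return a list of class `hc_run` with elements `vitals` (data.frame
#'   `time_s`, `pap_mmHg`, `dap_mmHg`, `cvp_mmHg`), `ticks` (per-decision
#'   records), `interventions` (flat data.frame), `report` (a
#'   [time_in_range()] + [intervention_stats()] summary over the
#'   critical-care phase), `schedule`, `seed`, `controller_enabled`, and the
#'   final controller and patient states.
#' @export
run_experiment <- function(params, config, schedule = NULL, seed = NULL,
                           controller = TRUE) {
  stopifnot(inherits(params, "patient_params"), inherits(config, "ctrl_config"))
  if (is.null(schedule)) schedule <- build_schedule(params$weight_kg,
                                                    params$ebv_ml_per_kg)
  validate_schedule(schedule)
  if (abs(attr(schedule, "weight_kg") - params$weight_kg) > 1e-9 ||
      abs(config$weight_kg - params$weight_kg) > 1e-9)
    stop("weight_kg must agree across params, config and schedule")
  if (!is.null(seed)) set.seed(seed)

  frame_s <- 60
  end_s <- max(schedule$end_s)
  cc <- schedule[schedule$action == "critical_care", ]
  hem <- schedule[schedule$action == "hemorrhage", ]
  tx <- schedule[schedule$action == "transfuse", ]
  ca <- schedule[schedule$action == "calcium", ]
  n_frames <- end_s / frame_s
  samples_per_frame <- round(frame_s * params$sample_hz)

  st <- patient_init(params)
  cs <- ctrl_state(ne_rate = params$ne_baseline)
  vitals <- matrix(NA_real_, nrow = n_frames * samples_per_frame, ncol = 4)
  colnames(vitals) <- c("time_s", "pap_mmHg", "dap_mmHg", "cvp_mmHg")
  ticks <- list()
  sched_events <- list(list(time_s = ca$start_s, action = "calcium",
                            note = "scheduled infusion; no hemodynamic effect"))

  bolus_rate <- 0          # mL/min while a bolus is infusing
  bolus_end <- -Inf
  lockout_until <- -Inf
  pending_assessment <- FALSE

  for (f in seq_len(n_frames)) {
    t0 <- (f - 1) * frame_s
    t1 <- f * frame_s
    tm <- (t0 + t1) / 2
    act <- actuation(
      ne_rate = if (controller) cs$ne_rate else params$ne_baseline,
      fluid_rate_ml_min = if (tm < bolus_end) bolus_rate else 0,
      blood_rate_ml_min = if (tm >= tx$start_s && tm < tx$end_s) tx$rate_ml_min else 0,
      hemorrhage_rate_ml_min = if (tm >= hem$start_s && tm < hem$end_s) hem$rate_ml_min else 0,
      occlusion_fraction = occlusion_at(tm, schedule),
      injury_drive = injury_drive_at(tm, schedule)
    )
    res <- sim_advance(st, params, act, frame_s)
    st <- res$state
    rows <- ((f - 1) * samples_per_frame + 1):(f * samples_per_frame)
    vitals[rows, ] <- as.matrix(res$samples)

    decide_now <- controller &&
      t1 >= cc$start_s + frame_s && t1 < cc$end_s &&
      t1 >= bolus_end && t1 >= lockout_until
    if (decide_now) {
      win_rows <- rows
      w <- vitals_window(time_s = t1,
                         map_avg = mean(vitals[win_rows, "pap_mmHg"]),
                         cvp_avg = mean(vitals[win_rows, "cvp_mmHg"]))
      d <- decide(w, cs, config)
      cs <- d$state
      kinds <- vapply(d$interventions, function(x) x$kind, "")
      if (any(kinds %in% c("fluid_bolus", "test_bolus"))) {
        b <- d$interventions[[which(kinds %in% c("fluid_bolus", "test_bolus"))[1]]]
        bolus_rate <- b$magnitude / (config$bolus_duration_s / 60)
        bolus_end <- t1 + config$bolus_duration_s
        lockout_until <- bolus_end + frame_s  # assessment window
      }
      ticks[[length(ticks) + 1L]] <- list(
        time_s = t1, map_avg = w$map_avg, cvp_avg = w$cvp_avg,
        zone = d$zone,
        interventions = d$interventions,
        ne_rate_after = cs$ne_rate,
        responsiveness = cs$responsiveness)
    }
  }

  vitals <- as.data.frame(vitals)
  interventions <- flatten_interventions(ticks)
  cc_vitals <- vitals[vitals$time_s > cc$start_s & vitals$time_s <= cc$end_s, ]
  bins <- bin_one_minute(cc_vitals$time_s, cc_vitals$pap_mmHg,
                         t0 = cc$start_s)
  report <- time_in_range(bins)
  istats <- intervention_stats(interventions,
                               window_s = c(cc$start_s, cc$end_s))
  report[names(istats)] <- istats

  structure(list(vitals = vitals, ticks = ticks,
                 interventions = interventions,
                 scheduled_events = sched_events,
                 report = report, schedule = schedule,
                 seed = seed, controller_enabled = controller,
                 final_controller_state = cs, final_patient_state = st,
                 params = params, config = config),
            class = "hc_run")
}

# Flatten per-tick intervention lists into one data.frame.
flatten_interventions <- function(ticks) {
  rows <- list()
  for (tk in ticks) {
    for (iv in tk$interventions) {
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = iv$time_s, kind = iv$kind, magnitude = iv$magnitude,
        branch = iv$branch, zone = tk$zone, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(time_s = numeric(), kind = character(),
                      magnitude = numeric(), branch = character(),
                      zone = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
print.hc_run <- function(x, ...) {
  cat("<hc_run> seed:", if (is.null(x$seed)) "none" else x$seed,
      "| controller:", if (x$controller_enabled) "enabled" else "disabled", "\n")
  r <- x$report
  cat(sprintf("  critical-care bins: %d | <60: %.1f%% | 60-70: %.1f%% | >70: %.1f%%\n",
              r$n_bins, r$pct_lt60, r$pct_60_70, r$pct_gt70))
  cat(sprintf("  interventions/h: %.2f | boluses: %.1f%% | titrations: %.1f%%\n",
              r$interventions_per_hour,
              ifelse(is.na(r$pct_boluses), NA, r$pct_boluses),
              ifelse(is.na(r$pct_titrations), NA, r$pct_titrations)))
  invisible(x)
}
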