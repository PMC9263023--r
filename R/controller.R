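#' Controller configuration
#'
#' Builds the configuration object for the closed-loop critical-care
#' controller.  Defaults encode the published decision thresholds: a
#' normotensive target band of 60--70 mmHg (inclusive), severe hypotension
#' below 50 mmHg, a titration target of 65 mmHg, weight-based 5 mL/kg
#' crystalloid boluses over 2 min, a fluid-responsiveness threshold of
#' +5 mmHg, and the high-norepinephrine/low-CVP corner thresholds of
#' 0.5 mcg/kg/min and 6 mmHg.
#'
#' @param weight_kg subject weight in kg (required; boluses are weight-based).
#' @param map_low,map_high normotension band bounds in mmHg, both inclusive.
#' @param map_severe severe-hypotension threshold in mmHg (exclusive below).
#' @param map_target titration target MAP in mmHg.
#' @param scaling_constant dimensionless constant of the titration formula.
#' @param branch_scale_factors named integer vector of per-branch scale
#'   factors for the titration formula.  Severe hypotension uses a larger
#'   factor than moderate hypotension and weaning.
#' @param bolus_dose crystalloid bolus dose in mL/kg.
#' @param bolus_duration_s bolus infusion duration in seconds.
#' @param responsiveness_delta MAP rise (mmHg) defining fluid responsiveness.
#' @param high_ne_threshold norepinephrine rate (mcg/kg/min) above which the
#'   normotension corner case is considered.
#' @param low_cvp_threshold CVP (mmHg) below which preload is considered low.
#' @param ne_max,ne_min norepinephrine rate clamp bounds (mcg/kg/min).
#'   `ne_max` doubles as the "maximum pressors" trigger of the
#'   pressor-resistance branch.
#' @param ne_sqrt_floor floor (mcg/kg/min) applied inside the square root of
#'   the titration formula so titration cannot lock at a zero rate.
#' @param reset_after_interventions,reset_after_s responsiveness reset rules:
#'   number of interventions or seconds since the last test bolus.
#' @param decision_period_s controller evaluation cadence in seconds.
#'
#' @return a list of class `ctrl_config`.
#' @export
#' @examples
#' cfg <- ctrl_config(weight_kg = 70)
#' cfg$bolus_dose * cfg$weight_kg  # 350 mL bolus volume
ctrl_config <- function(weight_kg,
                        map_low = 60, map_high = 70,
                        map_severe = 50, map_target = 65,
                        scaling_constant = 0.0072,
                        branch_scale_factors = c(severe_hypotension = 2L,
                                                 moderate_hypotension = 1L,
                                                 hypertension_wean = 1L),
                        bolus_dose = 5, bolus_duration_s = 120,
                        responsiveness_delta = 5,
                        high_ne_threshold = 0.5, low_cvp_threshold = 6,
                        ne_max = 1.0, ne_min = 0, ne_sqrt_floor = 0.02,
                        reset_after_interventions = 4L, reset_after_s = 3600,
                        decision_period_s = 60) {
  stopifnot(is.numeric(weight_kg), length(weight_kg) == 1L, weight_kg > 0)
  if (!(map_severe < map_low && map_low <= map_target && map_target <= map_high))
    stop("thresholds must satisfy map_severe < map_low <= map_target <= map_high")
  stopifnot(map_severe > 0, bolus_dose > 0, bolus_duration_s > 0,
            responsiveness_delta > 0, low_cvp_threshold > 0,
            high_ne_threshold > 0, ne_min >= 0, ne_min < ne_max,
            ne_sqrt_floor >= 0, scaling_constant > 0,
            reset_after_interventions >= 1, reset_after_s > 0,
            decision_period_s > 0)
  needed <- c("severe_hypotension", "moderate_hypotension", "hypertension_wean")
  if (!all(needed %in% names(branch_scale_factors)))
    stop("branch_scale_factors must name: ", paste(needed, collapse = ", "))
  if (any(branch_scale_factors < 1))
    stop("branch scale factors must be >= 1")
  structure(list(
    weight_kg = weight_kg,
    map_low = map_low, map_high = map_high,
    map_severe = map_severe, map_target = map_target,
    scaling_constant = scaling_constant,
    branch_scale_factors = branch_scale_factors,
    bolus_dose = bolus_dose, bolus_duration_s = bolus_duration_s,
    responsiveness_delta = responsiveness_delta,
    high_ne_threshold = high_ne_threshold,
    low_cvp_threshold = low_cvp_threshold,
    ne_max = ne_max, ne_min = ne_min, ne_sqrt_floor = ne_sqrt_floor,
    reset_after_interventions = as.integer(reset_after_interventions),
    reset_after_s = reset_after_s,
    decision_period_s = decision_period_s
  ), class = "ctrl_config")
}

#' Initial controller state
#'
#' @param ne_rate starting norepinephrine rate in mcg/kg/min.  Animals carry a
#'   low baseline infusion (0.02 mcg/kg/min) into critical care, so that is
#'   the natural starting point in simulation.
#' @return a list of class `ctrl_state` with the norepinephrine rate, bolus
#'   count, fluid-responsiveness status (`"unknown"`, `"responsive"` or
#'   `"non_responsive"`) and its bookkeeping fields.
#' @export
ctrl_state <- function(ne_rate = 0.02) {
  stopifnot(is.numeric(ne_rate), length(ne_rate) == 1L, ne_rate >= 0)
  structure(list(
    ne_rate = ne_rate,
    bolus_count = 0L,
    responsiveness = "unknown",
    interventions_since_test = 0L,
    last_test_time_s = NA_real_,
    active_test = NULL,           # list(baseline_map=, start_s=) while a test bolus is pending
    last_intervention_time_s = NA_real_
  ), class = "ctrl_state")
}

#' One-minute vitals window
#'
#' The controller's only physiologic input: trailing 60-s averages of the
#' proximal mean arterial pressure and the central venous pressure.
#'
#' @param time_s seconds since experiment start (window end).
#' @param map_avg mean proximal MAP over the trailing 60 s, mmHg.
#' @param cvp_avg mean CVP over the trailing 60 s, mmHg.
#' @param warmup logical; `TRUE` while fewer than 60 s of samples exist.
#' @return a list of class `vitals_window`.
#' @export
vitals_window <- function(time_s, map_avg, cvp_avg, warmup = FALSE) {
  structure(list(time_s = time_s, map_avg = map_avg, cvp_avg = cvp_avg,
                 warmup = isTRUE(warmup)),
            class = "vitals_window")
}

new_intervention <- function(kind, magnitude, branch, time_s) {
  list(kind = kind, magnitude = magnitude, branch = branch, time_s = time_s)
}

#' Classify a 1-min MAP average into a pressure zone
#'
#' Band boundaries follow the published definitions: hypotension below
#' 60 mmHg (severe below 50 mmHg), normotension 60--70 mmHg inclusive at both
#' ends, hypertension above 70 mmHg.
#'
#' @param map_avg 1-min averaged MAP in mmHg (finite, non-negative).
#' @param config a [ctrl_config()].
#' @return one of `"severe_hypo"`, `"moderate_hypo"`, `"normo"`, `"hyper"`.
#' @export
#' @examples
#' cfg <- ctrl_config(weight_kg = 70)
#' classify_map(60, cfg)   # "normo" (inclusive lower bound)
#' classify_map(49.99, cfg) # "severe_hypo"
classify_map <- function(map_avg, config) {
  if (!is.numeric(map_avg) || length(map_avg) != 1L || !is.finite(map_avg) ||
      map_avg < 0)
    stop("map_avg must be a single finite non-negative number, got: ",
         deparse(map_avg))
  if (map_avg < config$map_severe) "severe_hypo"
  else if (map_avg < config$map_low) "moderate_hypo"
  else if (map_avg <= config$map_high) "normo"
  else "hyper"
}

#' Norepinephrine titration step size
#'
#' Magnitude of one titration step:
#' `branch_scale * scaling_constant * |MAP - target| * sqrt(max(ne_rate, ne_sqrt_floor))`.
#' The floor inside the square root keeps the step non-zero when the current
#' rate is zero, so the controller can start an infusion from nothing.  The
#' caller applies the sign (increase vs. decrease) and clamps the resulting
#' rate to `[ne_min, ne_max]`.
#'
#' @param map_avg 1-min averaged MAP, mmHg.
#' @param ne_rate current norepinephrine rate, mcg/kg/min (>= 0).
#' @param branch_scale integer scale factor of the active branch (>= 1).
#' @param config a [ctrl_config()].
#' @return non-negative titration magnitude in mcg/kg/min.
#' @export
#' @examples
#' cfg <- ctrl_config(weight_kg = 70)
#' titration_delta(55, 0.04, 1, cfg)  # 0.0072 * 10 * 0.2 = 0.0144
titration_delta <- function(map_avg, ne_rate, branch_scale, config) {
  if (!is.finite(map_avg)) stop("map_avg must be finite")
  if (!is.finite(ne_rate) || ne_rate < 0) stop("ne_rate must be >= 0")
  if (branch_scale < 1) stop("branch_scale must be >= 1")
  branch_scale * config$scaling_constant * abs(map_avg - config$map_target) *
    sqrt(max(ne_rate, config$ne_sqrt_floor))
}

#' Assess fluid responsiveness after a test bolus
#'
#' A subject is fluid responsive when the 1-min averaged MAP rises by at
#' least `responsiveness_delta` (default 5 mmHg, inclusive) from the
#' pre-bolus baseline to the post-bolus assessment window.
#'
#' @param baseline_map 1-min MAP average immediately preceding the test bolus.
#' @param post_map 1-min MAP average ending 60 s after bolus completion.
#' @param config a [ctrl_config()].
#' @return `"responsive"` or `"non_responsive"`.
#' @export
assess_responsiveness <- function(baseline_map, post_map, config) {
  if (!is.finite(baseline_map) || !is.finite(post_map))
    stop("baseline_map and post_map must be finite")
  if (post_map - baseline_map >= config$responsiveness_delta) "responsive"
  else "non_responsive"
}

#' Reset fluid-responsiveness status when stale
#'
#' Responsiveness reverts to `"unknown"` after four interventions since the
#' last test bolus, or one hour after the last test bolus, so that the next
#' hypotensive episode triggers a fresh test.
#'
#' @param state a [ctrl_state()].
#' @param now_s current time in seconds.
#' @param config a [ctrl_config()].
#' @return the (possibly updated) state.
#' @export
maybe_reset_responsiveness <- function(state, now_s, config) {
  stale_count <- state$interventions_since_test >= config$reset_after_interventions
  stale_time <- !is.na(state$last_test_time_s) &&
    (now_s - state$last_test_time_s) >= config$reset_after_s
  if (stale_count || stale_time) {
    state$responsiveness <- "unknown"
    state$interventions_since_test <- 0L
  }
  state
}

# Clamp a candidate NE rate into [ne_min, ne_max].
clamp_ne <- function(ne, config) {
  min(max(ne, config$ne_min), config$ne_max)
}

#' One controller decision tick
#'
#' Maps a 1-min averaged MAP/CVP snapshot plus controller state to zero or
#' more interventions.  The decision tree:
#'
#' * **Normotension** (60--70 mmHg inclusive): no intervention, unless the
#'   subject is on a large norepinephrine dose (> 0.5 mcg/kg/min) with a low
#'   CVP (< 6 mmHg), in which case a weight-based fluid bolus is given
#'   (branch `normotension_corner`) to enable subsequent pressor weaning.
#' * **Hypertension** (> 70 mmHg): an opportunity to wean the pressor; the
#'   rate is decreased by one titration step, clamped at `ne_min`; no
#'   intervention if already at the floor.
#' * **Severe hypotension** (< 50 mmHg): a weight-based fluid bolus and a
#'   simultaneous norepinephrine increase in the same tick.
#' * **Moderate hypotension** (50--59 mmHg inclusive): driven by the
#'   fluid-responsiveness state.  Unknown: issue a 5 mL/kg test bolus and
#'   defer classification.  Responsive: fluid-avid (bolus).  Non-responsive:
#'   pressor-avid (norepinephrine increase), except the CVP-based fluid bolus
#'   (CVP below `low_cvp_threshold`: bolus instead, avoiding cyclic pressor
#'   increases) and the pressor-resistance branch (already at `ne_max`:
#'   attempt a bolus).
#'
#' A pending test bolus recorded in `state$active_test` is assessed first,
#' using the current window as the post-bolus measurement; the staleness
#' reset is applied before branch selection.  A test bolus zeroes the
#' interventions-since-test counter and stamps the test time; every other
#' emitted intervention increments the counter (the severe-hypotension
#' combined action counts once for reset purposes).
#'
#' @param window a [vitals_window()] with warm-up complete.
#' @param state a [ctrl_state()].
#' @param config a [ctrl_config()].
#' @return `list(interventions = <list of interventions>, state = <new state>,
#'   zone = <zone label>)`.  Each intervention has fields `kind`
#'   (`fluid_bolus`, `test_bolus`, `ne_increase`, `ne_decrease`), `magnitude`
#'   (mL for boluses, mcg/kg/min for titrations), `branch` and `time_s`.
#' @export
decide <- function(window, state, config) {
  if (isTRUE(window$warmup))
    stop("decide() requires a full 60-s window (warm-up incomplete)")
  if (!is.finite(window$map_avg) || window$map_avg < 0 ||
      !is.finite(window$cvp_avg))
    stop("invalid vitals at t=", window$time_s,
         ": map_avg=", window$map_avg, " cvp_avg=", window$cvp_avg)
  now <- window$time_s
  bolus_ml <- config$bolus_dose * config$weight_kg

  # settle a pending fluid-responsiveness test using this window as post-MAP
  if (!is.null(state$active_test)) {
    state$responsiveness <- assess_responsiveness(
      state$active_test$baseline_map, window$map_avg, config)
    state$active_test <- NULL
  }

  state <- maybe_reset_responsiveness(state, now, config)
  zone <- classify_map(window$map_avg, config)
  iv <- list()

  emit <- function(kind, magnitude, branch) {
    iv[[length(iv) + 1L]] <<- new_intervention(kind, magnitude, branch, now)
  }
  scale_of <- function(branch) unname(config$branch_scale_factors[[branch]])

  if (zone == "normo") {
    if (state$ne_rate > config$high_ne_threshold &&
        window$cvp_avg < config$low_cvp_threshold) {
      emit("fluid_bolus", bolus_ml, "normotension_corner")
      state$bolus_count <- state$bolus_count + 1L
    }
  } else if (zone == "hyper") {
    delta <- titration_delta(window$map_avg, state$ne_rate,
                             scale_of("hypertension_wean"), config)
    new_rate <- clamp_ne(state$ne_rate - delta, config)
    if (new_rate < state$ne_rate) {
      emit("ne_decrease", state$ne_rate - new_rate, "hypertension_wean")
      state$ne_rate <- new_rate
    }
  } else if (zone == "severe_hypo") {
    emit("fluid_bolus", bolus_ml, "severe_hypotension")
    state$bolus_count <- state$bolus_count + 1L
    delta <- titration_delta(window$map_avg, state$ne_rate,
                             scale_of("severe_hypotension"), config)
    new_rate <- clamp_ne(state$ne_rate + delta, config)
    if (new_rate > state$ne_rate) {
      emit("ne_increase", new_rate - state$ne_rate, "severe_hypotension")
      state$ne_rate <- new_rate
    }
  } else { # moderate_hypo
    if (state$responsiveness == "unknown") {
      emit("test_bolus", bolus_ml, "responsiveness_test")
      state$bolus_count <- state$bolus_count + 1L
      state$active_test <- list(baseline_map = window$map_avg, start_s = now)
      state$last_test_time_s <- now
      state$interventions_since_test <- 0L
    } else if (state$responsiveness == "responsive") {
      emit("fluid_bolus", bolus_ml, "moderate_hypotension_responsive")
      state$bolus_count <- state$bolus_count + 1L
    } else { # non_responsive
      if (window$cvp_avg < config$low_cvp_threshold) {
        emit("fluid_bolus", bolus_ml, "cvp_based_fluid_bolus")
        state$bolus_count <- state$bolus_count + 1L
      } else if (state$ne_rate >= config$ne_max) {
        emit("fluid_bolus", bolus_ml, "pressor_resistance")
        state$bolus_count <- state$bolus_count + 1L
      } else {
        delta <- titration_delta(window$map_avg, state$ne_rate,
                                 scale_of("moderate_hypotension"), config)
        new_rate <- clamp_ne(state$ne_rate + delta, config)
        if (new_rate > state$ne_rate) {
          emit("ne_increase", new_rate - state$ne_rate,
               "moderate_hypotension_nonresponsive")
          state$ne_rate <- new_rate
        }
      }
    }
  }

  if (length(iv) > 0L) {
    state$last_intervention_time_s <- now
    # a test bolus starts a fresh count; any other decision event counts once
    if (!any(vapply(iv, function(x) x$kind, "") == "test_bolus"))
      state$interventions_since_test <- state$interventions_since_test + 1L
  }
  list(interventions = iv, state = state, zone = zone)
}
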