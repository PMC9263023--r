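#' Synthetic patient parameters
#'
#' Parameter set for the lumped-parameter model of a swine subject undergoing
#' ischemia--reperfusion vasodilatory shock.  The model tracks circulating
#' blood volume (with a transient crystalloid pool subject to capillary
#' leak), vascular tone (which relaxes toward an injury-dependent setpoint
#' after reperfusion), and a first-order norepinephrine effect following a
#' Hill dose-response.  Pressures derive from a saturating preload-to-output
#' (Starling) relation and a systemic vascular resistance scaled by tone and
#' drug effect; an aortic occlusion fraction raises proximal afterload and
#' abolishes distal pressure.
#'
#' `svr_baseline` defaults to the value that places the model exactly at
#' equilibrium at full estimated blood volume (EBV = 60 mL/kg), baseline
#' vascular tone and the baseline norepinephrine infusion, so an uninjured
#' untreated patient sits at `baseline_map` by construction.
#'
#' @param weight_kg subject weight, kg.
#' @param ebv_ml_per_kg estimated total blood volume, mL per kg (60).
#' @param baseline_map equilibrium proximal MAP at baseline, mmHg.
#' @param cvp_base CVP at full estimated blood volume, mmHg.
#' @param venous_compliance venous compartment compliance, mL/mmHg.
#' @param cardiac_gain low-preload slope of the cardiac output curve,
#'   L/min per mmHg of CVP.
#' @param cvp_half CVP at which cardiac output reaches half its plateau, mmHg.
#' @param svr_baseline systemic vascular resistance at baseline, mmHg.min/L;
#'   `NULL` computes the equilibrium value described above.
#' @param ne_emax maximal fractional SVR gain from norepinephrine.
#' @param ne_ec50 norepinephrine rate producing half-maximal effect,
#'   mcg/kg/min.
#' @param ne_tau_s time constant of the drug effect, s.
#' @param ne_baseline baseline norepinephrine infusion, mcg/kg/min.
#' @param injury_tone_drop fractional loss of vascular tone at full
#'   reperfusion injury (0--1).
#' @param injury_tau_s,recovery_tau_s time constants (s) of tone relaxation
#'   toward a lower (injury) or higher (recovery) setpoint.
#' @param leak_rate fraction of the transient crystalloid pool lost per
#'   minute to capillary leak.
#' @param bolus_retention fraction of infused crystalloid retained
#'   intravascularly at steady state.
#' @param occ_gain fractional proximal afterload increase at full aortic
#'   occlusion.
#' @param noise_sd additive Gaussian measurement noise on arterial
#'   pressures, mmHg (per sample).
#' @param cvp_noise_sd measurement noise on CVP, mmHg.
#' @param ou_tau_s,ou_sigma time constant (s) and stationary SD of the slow
#'   Ornstein--Uhlenbeck drift on vascular tone.
#' @param dt_s integration step, s (0.1 by default).
#' @param sample_hz vitals recording rate, Hz (10 by default; 1000 matches
#'   clinical acquisition hardware but is rarely needed in simulation).
#' @return a list of class `patient_params`.
#' @export
patient_params <- function(weight_kg = 70,
                           ebv_ml_per_kg = 60,
                           baseline_map = 63.2,
                           cvp_base = 6,
                           venous_compliance = 250,
                           cardiac_gain = 4.1,
                           cvp_half = 1.5,
                           svr_baseline = NULL,
                           ne_emax = 1.5,
                           ne_ec50 = 0.12,
                           ne_tau_s = 90,
                           ne_baseline = 0.02,
                           injury_tone_drop = 0.35,
                           injury_tau_s = 450,
                           recovery_tau_s = 1800,
                           leak_rate = 0.08,
                           bolus_retention = 0.25,
                           occ_gain = 2,
                           noise_sd = 3,
                           cvp_noise_sd = 0.5,
                           ou_tau_s = 300,
                           ou_sigma = 0.03,
                           dt_s = 0.1,
                           sample_hz = 10) {
  stopifnot(weight_kg > 0, ebv_ml_per_kg > 0, baseline_map > 0, cvp_base > 0,
            venous_compliance > 0, cardiac_gain > 0, cvp_half > 0,
            ne_emax >= 0, ne_ec50 > 0, ne_tau_s > 0, ne_baseline >= 0,
            injury_tone_drop >= 0, injury_tone_drop < 1,
            injury_tau_s > 0, recovery_tau_s > 0,
            leak_rate >= 0, bolus_retention > 0, bolus_retention <= 1,
            occ_gain >= 0, noise_sd >= 0, cvp_noise_sd >= 0,
            ou_tau_s > 0, ou_sigma >= 0,
            dt_s > 0, dt_s <= 1, sample_hz > 0)
  if (abs(sample_hz * dt_s - round(sample_hz * dt_s)) > 1e-9 &&
      abs(1 / (sample_hz * dt_s) - round(1 / (sample_hz * dt_s))) > 1e-9)
    stop("sample_hz must be compatible with dt_s (1/(sample_hz*dt_s) integer)")
  p <- list(weight_kg = weight_kg,
            ebv_ml_per_kg = ebv_ml_per_kg,
            ebv_ml = ebv_ml_per_kg * weight_kg,
            baseline_map = baseline_map,
            cvp_base = cvp_base,
            venous_compliance = venous_compliance,
            cardiac_gain = cardiac_gain,
            cvp_half = cvp_half,
            ne_emax = ne_emax, ne_ec50 = ne_ec50,
            ne_tau_s = ne_tau_s, ne_baseline = ne_baseline,
            injury_tone_drop = injury_tone_drop,
            injury_tau_s = injury_tau_s, recovery_tau_s = recovery_tau_s,
            leak_rate = leak_rate, bolus_retention = bolus_retention,
            occ_gain = occ_gain,
            noise_sd = noise_sd, cvp_noise_sd = cvp_noise_sd,
            ou_tau_s = ou_tau_s, ou_sigma = ou_sigma,
            dt_s = dt_s, sample_hz = sample_hz)
  if (is.null(svr_baseline)) {
    co0 <- cardiac_gain * cvp_half * cvp_base / (cvp_base + cvp_half)
    ne_factor <- 1 + ne_emax * ne_baseline / (ne_baseline + ne_ec50)
    svr_baseline <- (baseline_map - cvp_base) / co0 / ne_factor
  }
  stopifnot(svr_baseline > 0)
  p$svr_baseline <- svr_baseline
  structure(p, class = "patient_params")
}

#' Initial patient state
#'
#' Initialises the synthetic patient at equilibrium: full tone, drug effect
#' at the baseline-infusion steady state, no drift, and a circulating volume
#' expressed as a fraction of estimated blood volume.
#'
#' @param params a [patient_params()].
#' @param volume_frac initial blood volume as a fraction of EBV.
#' @return a list of class `patient_state` with volume pools, vascular tone,
#'   drug effect, flow bookkeeping and the noiseless model pressures.
#' @export
patient_init <- function(params, volume_frac = 1) {
  stopifnot(inherits(params, "patient_params"), volume_frac > 0)
  st <- list(t_s = 0,
             v_blood_ml = params$ebv_ml * volume_frac,
             v_trans_ml = 0,
             vascular_tone = 1,
             ne_effect = params$ne_baseline / (params$ne_baseline + params$ne_ec50),
             tone_drift = 0,
             leak_cum_ml = 0, in_cum_ml = 0, out_cum_ml = 0)
  pr <- model_pressures(st, params, occlusion_fraction = 0)
  st$map_mmHg <- pr$map
  st$map_distal_mmHg <- pr$dap
  st$cvp_mmHg <- pr$cvp
  st$blood_volume_ml <- st$v_blood_ml + st$v_trans_ml
  structure(st, class = "patient_state")
}

# Noiseless model pressures for a given state (R mirror of the compiled
# kernel, used for initialisation and diagnostics).
model_pressures <- function(state, params, occlusion_fraction = 0) {
  v <- state$v_blood_ml + state$v_trans_ml
  cvp <- max(params$cvp_base + (v - params$ebv_ml) / params$venous_compliance, 0.1)
  co <- params$cardiac_gain * params$cvp_half * cvp / (cvp + params$cvp_half)
  tone_eff <- max(state$vascular_tone * (1 + state$tone_drift), 0.05)
  svr <- params$svr_baseline * tone_eff * (1 + params$ne_emax * state$ne_effect)
  map <- cvp + co * svr * (1 + params$occ_gain * occlusion_fraction)
  dap <- cvp + (map - cvp) * (1 - occlusion_fraction)
  list(map = max(map, 0), dap = max(dap, 0), cvp = cvp, co = co, svr = svr)
}

#' Default actuation record
#'
#' @param ne_rate norepinephrine infusion, mcg/kg/min.
#' @param fluid_rate_ml_min crystalloid infusion rate, mL/min.
#' @param blood_rate_ml_min blood (transfusion) rate, mL/min.
#' @param hemorrhage_rate_ml_min blood withdrawal rate, mL/min.
#' @param occlusion_fraction aortic occlusion fraction in `[0, 1]`.
#' @param injury_drive reperfusion-injury exposure in `[0, 1]`; the vascular
#'   tone setpoint is `1 - injury_tone_drop * injury_drive`.
#' @return a named list.
#' @export
actuation <- function(ne_rate = 0, fluid_rate_ml_min = 0,
                      blood_rate_ml_min = 0, hemorrhage_rate_ml_min = 0,
                      occlusion_fraction = 0, injury_drive = 0) {
  if (any(!is.finite(c(ne_rate, fluid_rate_ml_min, blood_rate_ml_min,
                       hemorrhage_rate_ml_min, occlusion_fraction,
                       injury_drive))))
    stop("actuation values must be finite")
  if (ne_rate < 0 || fluid_rate_ml_min < 0 || blood_rate_ml_min < 0 ||
      hemorrhage_rate_ml_min < 0)
    stop("actuation rates must be >= 0")
  if (occlusion_fraction < 0 || occlusion_fraction > 1)
    stop("occlusion_fraction must lie in [0, 1]")
  if (injury_drive < 0 || injury_drive > 1)
    stop("injury_drive must lie in [0, 1]")
  list(ne_rate = ne_rate, fluid_rate_ml_min = fluid_rate_ml_min,
       blood_rate_ml_min = blood_rate_ml_min,
       hemorrhage_rate_ml_min = hemorrhage_rate_ml_min,
       occlusion_fraction = occlusion_fraction,
       injury_drive = injury_drive)
}

#' Advance the synthetic patient
#'
#' Integrates the model forward by `duration_s` seconds under constant
#' actuation, using the fixed step `params$dt_s`, and records vitals at
#' `params$sample_hz`.  Measurement noise and the tone drift draw from R's
#' random number stream, so runs are reproducible under [set.seed()].
#'
#' @param state a [patient_init()] state.
#' @param params a [patient_params()].
#' @param act an [actuation()] record.
#' @param duration_s simulated duration, s (must be a multiple of `dt_s`).
#' @param record logical; record vitals samples?
#' @return `list(state = <new state>, samples = <data.frame with columns
#'   time_s, pap_mmHg, dap_mmHg, cvp_mmHg>)`.
#' @export
sim_advance <- function(state, params, act, duration_s, record = TRUE) {
  stopifnot(inherits(state, "patient_state"), inherits(params, "patient_params"))
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  n_steps <- round(duration_s / params$dt_s)
  if (abs(n_steps * params$dt_s - duration_s) > 1e-6)
    stop("duration_s must be a multiple of dt_s")
  act <- do.call(actuation, act[names(act) %in% names(formals(actuation))])
  record_every <- if (record) round(1 / (params$sample_hz * params$dt_s)) else 0L
  res <- .sim_chunk_cpp(state, params, act, as.integer(n_steps),
                        params$dt_s, as.integer(record_every))
  samples <- res$samples
  colnames(samples) <- c("time_s", "pap_mmHg", "dap_mmHg", "cvp_mmHg")
  list(state = res$state, samples = as.data.frame(samples))
}

#' Single integration step
#'
#' Thin wrapper over [sim_advance()] taking one step of `dt_s` seconds; the
#' returned sample (if recorded) is the instantaneous noisy measurement.
#'
#' @inheritParams sim_advance
#' @param dt_s step length, s, in `(0, 1]`.
#' @return as [sim_advance()].
#' @export
sim_step <- function(state, params, act, dt_s = params$dt_s) {
  if (!is.finite(dt_s) || dt_s <= 0 || dt_s > 1)
    stop("dt_s must lie in (0, 1]")
  p <- params
  p$dt_s <- dt_s
  p$sample_hz <- 1 / dt_s
  sim_advance(state, p, act, dt_s, record = TRUE)
}

#' Crystalloid bolus kinetics
#'
#' Infuses a bolus at constant rate over `duration_s`, then follows the
#' subsequent redistribution for `follow_s` seconds.  Intravascular volume
#' rises during infusion and decays toward `bolus_retention * bolus_ml`
#' above its starting value as the transient pool leaks.  The MAP response
#' measured the way the controller measures it (trailing 1-min average
#' before the bolus vs. the 1-min average ending 60 s after completion)
#' discriminates hypovolemia: depleted patients rise >= 5 mmHg, replete
#' patients do not.
#'
#' @param state a [patient_state][patient_init()].
#' @param params a [patient_params()].
#' @param bolus_ml bolus volume, mL (0 returns the state unchanged).
#' @param duration_s infusion duration, s.
#' @param follow_s post-infusion follow-up, s.
#' @param ne_rate constant norepinephrine rate during the maneuver.
#' @param injury_drive constant injury exposure during the maneuver.
#' @return `list(state, trajectory = <data.frame time_s, volume_ml,
#'   map_mmHg, cvp_mmHg>, delta_map = <baseline-to-assessment MAP change,
#'   mmHg, NA if follow_s < 60>)`.
#' @export
apply_bolus_kinetics <- function(state, params, bolus_ml, duration_s = 120,
                                 follow_s = 600, ne_rate = params$ne_baseline,
                                 injury_drive = 0) {
  stopifnot(inherits(state, "patient_state"), bolus_ml >= 0)
  if (bolus_ml == 0)
    return(list(state = state,
                trajectory = data.frame(time_s = numeric(), volume_ml = numeric(),
                                        map_mmHg = numeric(), cvp_mmHg = numeric()),
                delta_map = NA_real_))
  baseline <- sim_advance(state, params,
                          actuation(ne_rate = ne_rate, injury_drive = injury_drive),
                          60)
  base_map <- mean(baseline$samples$pap_mmHg)
  st <- baseline$state
  traj <- list()
  infuse <- sim_advance(st, params,
                        actuation(ne_rate = ne_rate,
                                  fluid_rate_ml_min = bolus_ml / (duration_s / 60),
                                  injury_drive = injury_drive),
                        duration_s)
  st <- infuse$state
  traj[[1]] <- infuse$samples
  post <- sim_advance(st, params,
                      actuation(ne_rate = ne_rate, injury_drive = injury_drive),
                      follow_s)
  st <- post$state
  traj[[2]] <- post$samples
  samples <- rbind(traj[[1]], traj[[2]])
  delta_map <- NA_real_
  if (follow_s >= 60) {
    assess <- samples$time_s > st$t_s - follow_s &
      samples$time_s <= st$t_s - follow_s + 60
    delta_map <- mean(samples$pap_mmHg[assess]) - base_map
  }
  vol <- approx_volume_trace(baseline$state, params, bolus_ml, duration_s,
                             samples$time_s)
  list(state = st,
       trajectory = data.frame(time_s = samples$time_s, volume_ml = vol,
                               map_mmHg = samples$pap_mmHg,
                               cvp_mmHg = samples$cvp_mmHg),
       delta_map = delta_map)
}

# Closed-form volume trace of a bolus (constant-rate infusion into the
# retained + transient pools with first-order leak), for reporting.
approx_volume_trace <- function(state0, params, bolus_ml, duration_s, times) {
  k <- params$leak_rate / 60
  r <- bolus_ml / duration_s
  t0 <- state0$t_s
  v0 <- state0$v_blood_ml + state0$v_trans_ml
  tr0 <- state0$v_trans_ml
  tt <- pmax(times - t0, 0)
  infusing <- pmin(tt, duration_s)
  retained <- params$bolus_retention * r * infusing
  trans_in <- (1 - params$bolus_retention) * r
  if (k > 0) {
    trans <- ifelse(tt <= duration_s,
                    tr0 * exp(-k * tt) + trans_in / k * (1 - exp(-k * tt)),
                    (tr0 * exp(-k * duration_s) +
                       trans_in / k * (1 - exp(-k * duration_s))) *
                      exp(-k * (tt - duration_s)))
  } else {
    trans <- tr0 + trans_in * infusing
  }
  v0 - tr0 + retained + trans
}
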