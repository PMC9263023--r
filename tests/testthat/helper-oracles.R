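# Independent oracles and shared fixtures for the suite.

# Brute-force median/quartiles by sorting and linear interpolation of order
# statistics (independent of stats::quantile): the p-th quantile of the
# sorted values x_(1..n) sits at rank h = (n - 1) p + 1.
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  sapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  })
}

# Deterministic patient: measurement noise and tone drift switched off, so
# kinetic contracts can be asserted without seed sensitivity.
quiet_params <- function(weight_kg = 70, ...) {
  patient_params(weight_kg = weight_kg, noise_sd = 0, cvp_noise_sd = 0,
                 ou_sigma = 0, ...)
}

default_cfg <- function(weight_kg = 70, ...) ctrl_config(weight_kg = weight_kg, ...)

# Bring a patient to a steady state at a given volume fraction and NE rate.
settled_state <- function(params, volume_frac, ne_rate = params$ne_baseline,
                          injury_drive = 0, settle_s = 300) {
  st <- patient_init(params, volume_frac = volume_frac)
  sim_advance(st, params,
              actuation(ne_rate = ne_rate, injury_drive = injury_drive),
              settle_s, record = FALSE)$state
}
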