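#include <Rcpp.h>
using namespace Rcpp;

// Lumped-parameter hemodynamics, shared by every step:
//   CVP  = cvp_base + (V - EBV)/C_v                     (floored near 0)
//   CO   = g * h * CVP / (CVP + h)                      (saturating Starling)
//   SVR  = svr0 * tone_eff * (1 + emax * E)             (NE effect E in [0,1))
//   MAP  = CVP + CO * SVR * (1 + occ_gain * occ)        (proximal)
//   DAP  = CVP + (MAP - CVP) * (1 - occ)                (distal, mean only)
static inline void pressures(double v_total, double tone_eff, double ne_effect,
                             double occ,
                             double cvp_base, double ebv, double venous_c,
                             double gain, double half, double svr0,
                             double emax, double occ_gain,
                             double *map, double *dap, double *cvp) {
  double c = cvp_base + (v_total - ebv) / venous_c;
  if (c < 0.1) c = 0.1;
  double co = gain * half * c / (c + half);
  double svr = svr0 * tone_eff * (1.0 + emax * ne_effect);
  if (svr < 0.0) svr = 0.0;
  double m = c + co * svr * (1.0 + occ_gain * occ);
  double d = c + (m - c) * (1.0 - occ);
  if (m < 0.0) m = 0.0;
  if (d < 0.0) d = 0.0;
  *map = m; *dap = d; *cvp = c;
}

// Advance the patient n_steps of dt seconds under constant actuation.
// Uses R's RNG (seed-controlled from R via set.seed) for measurement noise
// and the slow Ornstein-Uhlenbeck drift on vascular tone.  Samples are
// recorded every record_every steps; record_every = 0 records nothing.
// [[Rcpp::export(name = ".sim_chunk_cpp")]]
List sim_chunk_cpp(List state, List params, List act, int n_steps,
                   double dt, int record_every) {
  const double t0 = state["t_s"];
  double t        = t0;
  double v_blood  = state["v_blood_ml"];
  double v_trans  = state["v_trans_ml"];
  double tone     = state["vascular_tone"];
  double ne_eff   = state["ne_effect"];
  double drift    = state["tone_drift"];
  double leak_cum = state["leak_cum_ml"];
  double in_cum   = state["in_cum_ml"];
  double out_cum  = state["out_cum_ml"];

  const double ebv       = params["ebv_ml"];
  const double cvp_base  = params["cvp_base"];
  const double venous_c  = params["venous_compliance"];
  const double gain      = params["cardiac_gain"];
  const double half      = params["cvp_half"];
  const double svr0      = params["svr_baseline"];
  const double emax      = params["ne_emax"];
  const double ec50      = params["ne_ec50"];
  const double ne_tau    = params["ne_tau_s"];
  const double drop      = params["injury_tone_drop"];
  const double tau_inj   = params["injury_tau_s"];
  const double tau_rec   = params["recovery_tau_s"];
  const double leak_rate = params["leak_rate"];        // fraction/min
  const double retention = params["bolus_retention"];
  const double occ_gain  = params["occ_gain"];
  const double noise_sd  = params["noise_sd"];
  const double cvp_noise = params["cvp_noise_sd"];
  const double ou_tau    = params["ou_tau_s"];
  const double ou_sigma  = params["ou_sigma"];

  const double ne_rate  = act["ne_rate"];
  const double fluid    = as<double>(act["fluid_rate_ml_min"]) / 60.0;     // mL/s
  const double blood    = as<double>(act["blood_rate_ml_min"]) / 60.0;
  const double hem      = as<double>(act["hemorrhage_rate_ml_min"]) / 60.0;
  const double occ      = act["occlusion_fraction"];
  const double inj      = act["injury_drive"];

  const double hill = ne_rate / (ne_rate + ec50);
  const double tone_target = 1.0 - drop * inj;
  const double ou_a = std::exp(-dt / ou_tau);
  const double ou_b = ou_sigma * std::sqrt(1.0 - ou_a * ou_a);

  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericMatrix rec(n_rec, 4);
  int k = 0;

  for (int i = 0; i < n_steps; ++i) {
    // volume pools: retained fraction of crystalloid joins circulating
    // blood volume; the remainder is transient and leaks away
    double leak = v_trans * (leak_rate / 60.0) * dt;
    double hem_out = hem * dt;
    double v_tot = v_blood + v_trans;
    if (hem_out > v_tot) hem_out = v_tot;
    v_blood += (blood + fluid * retention) * dt - hem_out;
    if (v_blood < 0.0) v_blood = 0.0;
    v_trans += fluid * (1.0 - retention) * dt - leak;
    if (v_trans < 0.0) v_trans = 0.0;
    leak_cum += leak;
    in_cum += (blood + fluid) * dt;
    out_cum += hem_out;

    // first-order vascular tone toward the injury-dependent setpoint
    double tau = (tone_target < tone) ? tau_inj : tau_rec;
    tone += (tone_target - tone) / tau * dt;

    // first-order norepinephrine effect toward the Hill response
    ne_eff += (hill - ne_eff) / ne_tau * dt;

    // slow OU drift on tone (physiologic variability between 1-min bins)
    drift = drift * ou_a + ou_b * R::norm_rand();

    t = t0 + (i + 1) * dt;   // avoid accumulated rounding over long runs

    if (record_every > 0 && ((i + 1) % record_every == 0)) {
      double m, d, c;
      double tone_eff = tone * (1.0 + drift);
      if (tone_eff < 0.05) tone_eff = 0.05;
      pressures(v_blood + v_trans, tone_eff, ne_eff, occ,
                cvp_base, ebv, venous_c, gain, half, svr0, emax, occ_gain,
                &m, &d, &c);
      rec(k, 0) = t;
      rec(k, 1) = m + noise_sd * R::norm_rand();
      rec(k, 2) = d + noise_sd * R::norm_rand();
      rec(k, 3) = c + cvp_noise * R::norm_rand();
      if (rec(k, 1) < 0.0) rec(k, 1) = 0.0;
      if (rec(k, 2) < 0.0) rec(k, 2) = 0.0;
      if (rec(k, 3) < 0.0) rec(k, 3) = 0.0;
      ++k;
    }
  }

  double m, d, c;
  double tone_eff = tone * (1.0 + drift);
  if (tone_eff < 0.05) tone_eff = 0.05;
  pressures(v_blood + v_trans, tone_eff, ne_eff, occ,
            cvp_base, ebv, venous_c, gain, half, svr0, emax, occ_gain,
            &m, &d, &c);

  List out_state = List::create(
    _["t_s"] = t, _["v_blood_ml"] = v_blood, _["v_trans_ml"] = v_trans,
    _["vascular_tone"] = tone, _["ne_effect"] = ne_eff,
    _["tone_drift"] = drift, _["leak_cum_ml"] = leak_cum,
    _["in_cum_ml"] = in_cum, _["out_cum_ml"] = out_cum,
    _["map_mmHg"] = m, _["map_distal_mmHg"] = d, _["cvp_mmHg"] = c,
    _["blood_volume_ml"] = v_blood + v_trans);
  out_state.attr("class") = "patient_state";
  return List::create(_["state"] = out_state, _["samples"] = rec);
}
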