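---
title: "Closed-loop critical care on a synthetic ischemia–reperfusion patient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop critical care on a synthetic ischemia–reperfusion patient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemocontrol)
```

## The problem

Vasodilatory shock after aortic occlusion and reperfusion kills by sustained
hypotension. A rule-based controller that reads mean arterial pressure (MAP)
and central venous pressure (CVP) once a minute can titrate a norepinephrine
infusion and deliver weight-based crystalloid boluses without a clinician in
the loop. `hemocontrol` implements such a controller together with a
synthetic swine patient, so the complete closed loop — injury, monitoring,
decision, actuation — can be exercised, stress-tested and extended entirely
in software.

## The decision engine

The controller evaluates the trailing 1-min averages of MAP and CVP every
60 s and classifies MAP into four zones: severe hypotension (< 50 mmHg),
moderate hypotension (50–59 mmHg inclusive), normotension (60–70 mmHg
inclusive at both ends) and hypertension (> 70 mmHg).

* **Normotension** produces no intervention, except in one corner: a large
  norepinephrine dose (> 0.5 µg/kg/min) combined with a low CVP (< 6 mmHg).
  The corner condition is well defined but the published action is not; we
  give a weight-based fluid bolus (branch `normotension_corner`), on the
  view that restoring preload is what lets the pressor be weaned afterwards.
* **Hypertension** is an opportunity to wean the pressor by one titration
  step, clamped at the dose floor. Fluids are never withdrawn; a subject at
  zero norepinephrine and MAP > 70 receives nothing.
* **Severe hypotension** triggers a 5 mL/kg crystalloid bolus and a
  simultaneous norepinephrine increase in the same decision tick.
* **Moderate hypotension** is governed by a fluid-responsiveness state
  machine. With status *unknown* the controller gives a 5 mL/kg test bolus
  over 2 min and classifies the subject *responsive* if the 1-min MAP
  average rises by ≥ 5 mmHg (inclusive) from the pre-bolus baseline to the
  window ending 60 s after the infusion. Responsive subjects get fluid-avid
  care (boluses); non-responsive subjects get pressor-avid care, with two
  exceptions: a CVP below 6 mmHg diverts to a fluid bolus (avoiding cyclic
  pressor escalation in an empty circulation), and a subject already at the
  maximum rate receives a bolus as well (the pressor-resistance path).
  After four interventions, or one hour since the last test bolus, the
  status resets to *unknown* and the next hypotensive episode re-tests.

### The titration step

The published ingredients of the titration formula are the absolute MAP
deviation from the 65 mmHg target, the square root of the current
norepinephrine rate, a small integer branch scale factor and the constant
0.0072, but not their composition. We use the simplest form consistent
with all four:

$$\Delta = s \times 0.0072 \times |MAP - 65| \times \sqrt{\max(r,\ r_0)}$$

with $r$ the current rate in µg/kg/min and $r_0 = 0.02$ µg/kg/min a floor
inside the square root (equal to the baseline maintenance infusion) so that
titration cannot lock at a zero rate. Branch scale factors default to 2 for
severe-hypotension increases and 1 elsewhere — a larger correction for a
larger deviation. All of this is exposed in `ctrl_config()`. The step is
zero at target, monotone in both the deviation and the current rate, and
gentle in the mild ranges (at $r = 0.3$ and MAP 72 the wean step is about
0.03 µg/kg/min), which keeps the loop stable at the 1-min cadence.

### Cadence, lockouts and degenerate input

Decisions fire every 60 s (`decision_period_s`). No decision is taken while
a bolus is infusing, and after any bolus the next decision waits for the
60-s assessment window to close, so boluses are spaced at least 3 min
apart. The first 60 s of any stream are warm-up and produce no decisions.
Non-finite or negative pressures invalidate the tick: it is logged and
skipped, never imputed. Norepinephrine rates are clamped to
`[ne_min, ne_max]` after every change; `ne_max` (default 1.0 µg/kg/min,
above the 0.5 "large dose" marker) doubles as the pressor-resistance
trigger and must therefore be explicit.

## The synthetic patient

The simulator is deliberately minimal — a test harness with interpretable
knobs, not a physiological claim. It tracks:

* **Volume**: a circulating pool plus a transient crystalloid pool. A
  fraction `bolus_retention` (0.25) of infused crystalloid joins the
  circulating pool; the rest leaks away at `leak_rate` (8 %/min of the
  transient pool), so a bolus raises volume during infusion and then decays
  toward its retained fraction. Blood (hemorrhage, transfusion) moves the
  circulating pool directly.
* **Preload and output**: CVP is linear in volume (compliance 250 mL/mmHg,
  6 mmHg at full estimated blood volume, EBV = 60 mL/kg); cardiac output
  follows a saturating Starling curve (initial slope 4.1 L/min/mmHg,
  half-saturation 1.5 mmHg, ≈ 4.9 L/min at baseline for 70 kg). The
  saturation constants are what make the ≥ 5 mmHg bolus criterion
  discriminating: below ~85 % EBV a 5 mL/kg bolus moves MAP well over
  5 mmHg, at or above full volume it does not.
* **Tone and drug effect**: systemic vascular resistance is the baseline
  value (set so the uninjured patient sits exactly at its 63.2 mmHg
  baseline MAP) scaled by vascular tone and by a first-order norepinephrine
  effect with Hill steady state ($E_{max}$ 1.5, EC50 0.12 µg/kg/min,
  τ = 90 s). Reperfusion injury drags the tone setpoint down by 35 % with a
  450-s time constant as the balloon weans; under these defaults the
  untreated patient settles near MAP 41 mmHg — deep vasodilatory shock that
  the controller must actively reverse, and can (a rate near
  0.27 µg/kg/min restores the band, comfortably inside the clamp).
* **Aortic occlusion**: the occlusion fraction multiplies proximal
  afterload (tripling it at full occlusion) and scales distal pressure to
  CVP, reproducing the loss of distal perfusion during balloon inflation.
* **Noise**: additive Gaussian measurement noise (3 mmHg per sample at
  10 Hz, largely averaged out in 1-min bins) plus a slow
  Ornstein–Uhlenbeck drift on tone (sd 3 %, τ = 300 s) that moves 1-min
  bins by a couple of mmHg — the component that makes band-crossings, and
  occasional responsiveness misclassifications, possible at all.

Integration is explicit Euler at `dt_s = 0.1` s with vitals recorded at
10 Hz; a 1000 Hz mode exists for parity with clinical acquisition hardware
but adds nothing at this model's bandwidth. Volume bookkeeping is exact by
construction (inflows − outflows − leak), and runs are bit-reproducible
given a seed.

### What the simulator does not capture

No pulse waveform morphology, no oxygen transport or lactate kinetics, no
baroreflex, no renal or coagulation physiology, and much less spontaneous
variability than a live animal. Two consequences matter when reading
results. First, passing the design-goal simulation shows the decision logic
is sufficient *for this model class*; it is not evidence about animals.
Second, the synthetic patient is steadier than real swine, so the
controller intervenes at roughly 3 per hour where animal cohorts ran near
8.5 per hour — the intervention-rate statistic is reported, not matched.

## The experiment choreography

`build_schedule()` encodes the standard injury timeline: 30 % EBV
hemorrhage over minutes 0–30; complete aortic occlusion 30–60; a calcium
gluconate infusion at minute 45 (scheduled and logged, hemodynamically a
no-op); transfusion back to 95 % EBV from minute 55 over 18 min; a linear
balloon wean 60–75 (the published wean is "programmatic" without a stated
profile; linear is the least-assuming choice); then 255 min of closed-loop
critical care ending 5.5 h after start. Transfusion targets 95 % of
*estimated* blood volume (the alternative reading, 95 % of measured
pre-hemorrhage volume, is indistinguishable here because the model starts
at exactly EBV). The controller is active only in the critical-care
window; its first decision uses the window ending 60 s after the phase
starts.

## Metrics

High-rate MAP is reduced to consecutive 1-min bins (trailing partial bins
dropped; bin values are plain arithmetic means, and a sample on a bin's
right edge belongs to that bin). Bands are hypotension < 60, normotension
60–70 inclusive, hypertension > 70, with the hypertensive band split at
80 mmHg (80 itself in the lower sub-band; 70 belongs to normotension, so
the sub-bands partition exactly). Cohort roll-ups are medians with
25th/75th percentiles using linear-interpolation order statistics
(`quantile` type 7), the convention under which the packaged five-animal
fixture reproduces its published summary (15.3 %, IQR 8.6–16.9 % time
hypotensive) exactly; for n = 5 these quartiles are the 2nd and 4th order
statistics. Intervention statistics count test boluses as boluses and
every norepinephrine change, up or down, as one titration. The first-hour
sub-analysis reuses the same bins with an offset window. Exclusion screens
flag expiration (MAP < 20 mmHg sustained 5 min), excessive setup pressor
(> 0.1 µg/kg/min beyond 10 min cumulative) and baseline pressor dependence
(> 0.06 µg/kg/min at time zero); the white-cell criterion needs laboratory
data and is out of scope.

## Problem sizes and evaluation

The design-goal evaluation in the test-suite and acceptance script uses 20
seeded runs of the full 5.5-h experiment at dt = 0.1 s (about 0.4 s per
run): the median fraction of critical-care bins at or above 60 mmHg should
be at least 90 % with less than 20 % above 70 mmHg, and under the defaults
the closed loop achieves ≈ 93 % and 0 %. Controller necessity is checked
on paired seeds: untreated runs are > 50 % hypotensive and every treated
run is strictly better. Property suites fuzz the decision tree (rate
clamping, zone partition, reset logic) and check the simulator against
independent oracles (volume bookkeeping, brute-force order statistics,
hand titration arithmetic).

## Known limitations

The titration composition and branch-scale assignment are reconstructions
of a published ingredient list; alternative compositions with the same
ingredients would differ at extreme rates. The normotension-corner action
is our design choice. The simulator's injury severity is calibrated to the
qualitative contract (untreated collapse below 60 mmHg; treatable within
the dose clamp), not to any published trajectory. None of the cohort-level
outputs should be read as predictions about animals.
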