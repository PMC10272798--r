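---
title: "cuffsim: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cuffsim: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, the choices made where the
formulation was genuinely open, and what the simulations can and cannot
say about real measurements.

## The physical picture

A brachial cuff inflating at a constant rate modulates the circulation of
the arm distal to it in stages. Below the venous collapse pressure
(~30 mmHg) nothing changes. Past it, the vein under the cuff shuts while
arterial inflow continues, so blood accumulates distally and the distal
venous pressure climbs slowly (the venous compartment is ~30 times more
compliant than the arterial one, so this filling has a time constant of
roughly `R_systemic * C_ven` ~ 90 s). Once the cuff pressure approaches
diastolic pressure, the arterial segment under the cuff starts to pinch
shut at every diastole while still opening at systole: it acts as a
pressure-gated valve, rectifying the pulse, so the distal diastolic and
mean pressures are pushed up toward the systolic envelope while the
distal pulse amplitude shrinks. Finally, above systolic pressure, flow
stops entirely and both distal compartments relax exponentially — with
time constant `R_systemic * (C_art*C_ven)/(C_art+C_ven)` ~ 3 s — to a
common equilibrium `P_eq`, the compliance-weighted mean of the pressures
at occlusion.

On the measurement side, the same off-loading of the artery under the
cuff slows the pulse there (longer pulse arrival time at the finger),
while the distal pressurization *speeds* the pulse over the distal
segment (shorter distal transit time). The six response metrics
(`response_metrics()`) quantify both families of effects per inflation.

## Circuit model

Two ODEs (explicit in `simulate_arm()`'s compiled core) describe the
distal arterial and venous node pressures, driven by an ideal sinusoidal
systemic pressure defined by SBP, PP and heart rate, and by the cuff
ramp. All circuit constants are fixed at their reference values
(`circuit_params()`): `R_systemic` = 100 mmHg·s/mL, `C_art` =
0.03 mL/mmHg, `C_ven` = 30 × `C_art`, venous collapse centred at
30 mmHg. The venous collapse is a log-space sigmoid between the open
value (10 mmHg·s/mL, uncritical) and the occlusion cap, with a 2 mmHg
transition scale: the exact shape is unimportant, smoothness helps the
integrator. Note that with the vein open the distal venous node rests at
the divider value `(P_a/R_sys + P_ven,sys/R_ven)/(1/R_sys + 1/R_ven)`
(about 18 mmHg at reference), above the 10 mmHg systemic venous source —
the pressure drop over the venous outflow resistance at resting flow.

### The tube law and its normalization

The collapsible-tube law used for both the segment resistance and the
wave speed is

$$A(P_{tm}) = d\,\left[\frac{\ln(a P_{tm} + 3.3)}{\ln 3.3}\right]^{1 + e^{-c P_{tm}}}.$$

The bracket is normalized to equal 1 at zero transmural pressure, so `d`
is literally the lumen area at `P_tm = 0` (0.08 cm², i.e. a 1.6 mm
brachial radius). This normalization is a deliberate design choice with
three consequences that we consider essential to the physics:

* the law is globally monotone non-decreasing in `P_tm`, so the
  compliance `dA/dP` is non-negative everywhere and the Bramwell–Hill
  wave speed is real. The un-normalized variant (bracket not divided by
  `ln 3.3`) is *not* monotone — its area dips by ~1.6% in a band around
  `P_tm` ≈ 0–25 mmHg at reference parameters, where its total derivative
  turns negative and wave speeds become imaginary;
* the collapse is anchored at the knee `P_tm ≈ 0` for *every* value of
  `a`, because the bracket crosses 1 exactly where the log argument
  crosses 3.3. The un-normalized variant collapses where `ln(aP+3.3)`
  crosses 1, i.e. at `P_tm = (e−3.3)/a`, which moves from −17 to
  −34 mmHg across the sampled `a` range and would make `a` — not blood
  pressure — a dominant driver of the arrival-time and onset metrics,
  contradicting the global sensitivity structure this model is meant to
  exhibit (collapse-parameter influence marginal everywhere);
* an artery that starts to buckle as soon as its transmural pressure
  turns negative is the physiologically expected behaviour.

`a` (collapse slope) and `c` (collapse steepness) retain their meaning;
reference values `a = 0.03`, `c = 0.1` mmHg⁻¹.

### Transmural pressure convention

The segment under the cuff spans a pressure drop, so "arterial pressure
minus cuff pressure" is ambiguous. We evaluate `R_art` at the *proximal*
(systemic) pressure minus cuff pressure. The alternatives fail
structurally: referencing the *distal* node couples the valve to the
downstream state, so a falling distal pressure chokes its own inflow and
the distal compartment crashes instead of filling; referencing the
*midpoint* feeds half of that same feedback in and quenches the filling
effect to a fraction of its observed size while delaying its onset. The
proximal convention is the vascular-waterfall picture: the upstream
pulse gates the collapsed segment open at systole regardless of what is
downstream, and blocks backflow at diastole. `simulate_arm()` exposes
all three (`ptm_reference`).

## Pulse transit model

Clinical fiducials are waveform feet, so all transit evaluations use
per-beat diastolic pressures: the cuff segment at
`mean(systemic DBP, distal DBP) − P_cuff` over the cuff length, the
distal segment at the distal DBP over the remaining arm length, both via
Bramwell–Hill `PWV = sqrt(A (dP/dA) / ρ)` with mmHg→Pa conversion and
blood density 1060 kg/m³ (blood viscosity, needed by the Poiseuille
resistance, is 3.5 mPa·s = 2.63e-5 mmHg·s; neither is a printed model
constant, both are standard physiological values exposed in
`blood_properties()`).

Two further choices shape this stage:

* **Sub-buckling wave speed floor.** The distension-branch Bramwell–Hill
  speed falls steeply below the knee and would make the last measurable
  arrival times hypersensitive to where the beat grid happens to sample
  the collapse. Physically, transmission through a buckled segment
  happens at the collapsed-lobe wave speed, which is of the order of the
  knee minimum (~2.9 m/s at reference), not arbitrarily slow. We
  therefore hold `pulse_wave_velocity()` at its knee value for
  `P_tm < 0` until the lumen clamps shut entirely, where the segment
  stops transmitting. Without the floor, the pulse-pressure draw — via
  the stop pressure `−PP/2` — would dominate the maximum PAT change,
  instead of cuff length.
* **Fixed measurement calibration in the sensitivity batch.**
  `run_model_batch()` evaluates the per-beat transit times with the
  *reference* tube-law constants for every sampled row (argument
  `ptt_tube`): the emulated measurement chain has one wave-speed
  calibration and does not track the sampled vessel, so the sampled
  collapse parameters act on the PTT/PAT metrics only through the
  simulated pressures. With the sampled law inside the transit stage,
  `a` would contribute first-order indices of 0.1–0.5 to the transit
  metrics purely through the `1/a` factor of the Bramwell–Hill speed —
  a calibration artifact, not circuit physics. Single-run analyses
  (`ptt_series()`) default to the simulation's own law.

## Metrics and detection rules

* Baseline = mean over the last 5 pre-inflation beats (beats are one
  cardiac period, aligned to the troughs of the systemic sinusoid).
* `max|dMAP|`, `max|dDBP|`: maximum per-beat rise of the distal MAP/DBP
  above baseline. Note the passive circuit bounds the distal MAP by the
  systemic SBP, so `max|dMAP|` cannot exceed ~PP/2.
* `max|dPTT_distal|`: largest per-beat drop of the distal transit time;
  the distal decomposition stays defined after finger pulses vanish
  (it is model-internal), which keeps onset detection well-posed at
  fast inflation rates.
* `max|dPAT_total|`: largest absolute total arrival-time change over
  beats whose cuff segment still transmits (cuff pressure below
  systemic SBP and lumen not clamped at the evaluation pressure).
* `P_eq`: distal arterial pressure at hold end, guarded by
  `|dP/dt| < 0.01 mmHg/s` *and* residual pulsation < 0.1 mmHg over the
  final second (the slope alone is blind to a purely periodic residual).
* `dPTT_onset`: systemic MAP minus the cuff pressure at the onset of the
  distal PTT decrease. Onset = first beat of 3 consecutive beats with a
  drop below 0.5 ms (normalized to the 0.86 m reference distal path),
  with the crossing interpolated linearly between beats. The threshold
  sits above the slow venous-creep contribution (~0.2 ms) so detection
  keys on the fast knee-phase drop; the length normalization keeps a
  geometry split from changing the detector's sensitivity; and the
  sub-beat interpolation removes the 4–8 mmHg quantization that one
  beat of ramp otherwise injects into the metric.

## Sensitivity analysis

The six-parameter study space (`table2_specs()`): `a` ~ U(0.017, 0.035),
`c` ~ U(0.08, 0.14), SBP ~ N(125, 15), PP ~ N(40, 5) (untruncated;
draws with DBP within 5 mmHg of venous pressure are flagged invalid and
excluded pairwise — a per-mille occurrence), inflation rate ~ U(4, 8)
mmHg/s, cuff length ~ U(0.10, 0.18) m. Heart rate stays at 60 bpm and
all circuit constants at reference.

Sampling is a Saltelli radial design on the Sobol' sequence (Joe–Kuo
direction numbers, Gray-code order, implemented in `sobol_points()`;
the first `n` points are skipped, which keeps the power-of-two balance
and avoids the origin under the inverse-normal map; a seeded binary
digital shift randomizes the sequence without disturbing its balance).
First-order indices use the Saltelli-2010 estimator, total-order the
Jansen estimator, both normalized by the pooled A/B variance, with
bootstrap confidence half-widths over the base-sample rows. The
estimators are validated against the analytic Ishigami and g-function
benchmarks in the test suite.

Problem sizes: the acceptance script uses base n = 512 (4096 model
runs, ~1.5 min); the test suite uses n = 256 for the end-to-end checks
and 2^12–2^14 for the analytic benchmarks. Quasi-Monte-Carlo index
estimates at n = 256–512 carry sampling uncertainty of a few hundredths,
which is well inside the tolerance used to compare dominance structure.

## Virtual experiments

`experiment_cuff_length()` and `experiment_bp_correlation()` regress
metrics on parameters over *all* valid sampled rows of the same design
(the sampled sets are the experiment); `experiment_inflation_rate()` is
a controlled sweep of the rate over 4–8 mmHg/s at reference values —
the marginal effect at reference, which is the cleaner reading of a
rate effect, though the regression route over the sampled sets is
available from the design as well.

## Synthetic measurement chain

`synthesize_recording()` emulates the clinical chain only as far as
interval measurement needs: an ECG-like impulse train at 500 Hz, the
distal pressure as an ABP-like trace at 125 Hz delayed by a constant
conduction offset, and a PPG-like channel built from a low-pass-filtered
normalized copy of the distal pulse delayed additionally by the per-beat
total transit time, with the inserted delays recorded as ground truth
and optional white noise. Feet are detected by intersecting tangents
(max-upslope tangent, fitted by local regression on a smoothed window,
intersected with the pre-upstroke minimum level). The round trip
recovers the inserted delay ramp to within two PPG samples at zero
noise. What this does *not* emulate: realistic ECG/PPG morphology,
motion and breathing artifacts, baseline wander, or beat-form change
under the cuff — so passing round-trip tests says the *interval
pipeline* is correct, not that detection would perform equally on
clinical signals.

## Numerical choices

* Integrator: fixed-step explicit Euler at dt = 0.5 ms (RK4 available);
  the fastest circuit time constant (`R_art C_art` ~ 13 ms at rest)
  keeps `λ·dt` ~ 0.04. Halving the step changes no pressure sample by
  more than 0.1 mmHg on the reference run. A 10 s pre-roll (discarded)
  starts the state near `{MAP, P_ven,sys}`.
* Clamps: lumen floor `1e-6` cm² (the law is undefined once its log
  argument reaches 1), resistance cap `1e9` mmHg·s/mL; the compliance is
  a central finite difference with h = 0.01 mmHg, clamped inside the
  stencil, so it is exactly zero across the collapsed plateau.
* Default protocol: inflation starts at t = 6 s (five baseline beats at
  60 bpm), ramps to SBP + 50 mmHg (guaranteeing occlusion for any draw)
  and holds 60 s (20 relaxation time constants) so `P_eq` is a measured
  asymptote, not an extrapolation.
* Degenerate inputs: `dt` above 1 ms, non-positive parameters, SBP ≤ PP,
  or DBP at/below venous pressure raise immediately; protocols that
  never occlude fail the `P_eq` convergence guard rather than returning
  a meaningless number.

## Known limitations

* The distal filling effect this circuit produces is moderate
  (`max|dMAP|` of a few mmHg, `max|dDBP|` up to ~PP/2 at reference);
  clinically reported MAP rises of tens of mmHg are out of reach of the
  passive two-compartment topology, whose distal MAP is bounded by the
  systemic systolic envelope.
* The simulated maximum PAT change is almost fully determined by cuff
  length (first-order index ~0.9, regression R² ~0.92): the idealized
  metric extraction has no measurement noise and the floored sub-knee
  wave speed leaves little residual scatter, so length-dominance is
  *over*-expressed relative to measurement chains that carry beat-level
  noise. Treat the cuff-length dependence as directionally and
  rank-order robust, its residual structure as idealized.
* One tube segment per region: no axial variation of collapse along the
  cuff, no wave reflection, no viscoelasticity, no deflation protocols,
  and no oscillometric envelope extraction from cuff air pressure.
* The vein collapses as a function of cuff pressure only; a venous
  pressure buildup beyond the cuff pressure does not reopen it.
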