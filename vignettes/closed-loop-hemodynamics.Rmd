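---
title: "A closed-loop atrioventricular-aortic simulator and its pulse wave analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop atrioventricular-aortic simulator and its pulse wave analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulserig)
```

## The model

`pulserig` simulates the hemodynamics of a coupled left atrium (LA) - left
ventricle (LV) - aorta hydraulic loop of the kind used on benchtop
circulatory rigs: a compliant ventricular sac squeezed by a pulsatile pump,
a prosthetic aortic valve feeding a human-scale elastomer aorta with its
major branches, outlet units (air syringes and clamps) standing in for the
truncated vascular beds, a pair of air chambers acting as the arterial
reservoir, and an open venous tank returning fluid to the atrium through a
mechanical mitral valve. The working fluid is water at room temperature
(density 998 kg/m^3, viscosity 0.00089 Pa s).

The state of the model is a vector of volumes and flows integrated with a
fixed-step fourth-order Runge-Kutta scheme (default `dt` = 0.1 ms):

* **Ventricle.** A time-varying elastance, `P_lv = E(t) (V_lv - V0)`. The
  activation `E(t)` is periodic with period `60/hr`: a raised-cosine
  upstroke over the first 45% of the systolic interval, a raised-cosine
  decay over the remainder, then a diastolic plateau at `E_min`. It has a
  continuous first derivative, evaluates to `E_min` at the cycle start and
  to `E_min + contractility_scale (E_max - E_min)` at the activation peak.
  `contractility_scale` multiplies only the excursion, so doubling it
  doubles `E(t) - E_min` pointwise; matched-output comparisons across
  contractility levels are made with `calibrate_co()`, a bounded secant
  iteration on `E_max` (at most a handful of simulations), because the pump
  is neither a flow source nor a pressure source and cardiac output is an
  emergent quantity.
* **Valves.** Smoothed diodes. The conductance is logistic in the pressure
  drop, `g(dp) = 1 / (R_open (1 + exp(-dp/w)))` with transition width
  `w = 0.5` mmHg; the flow is `max(0, dp) g(dp)`, clamped so the valve
  never carries backflow and a loop at rest carries no leak. Defaults:
  aortic `R_open` 0.04, mitral 0.012 mmHg s/mL (a low mitral resistance is
  required for the ventricle to fill within a 0.4-0.5 s diastole).
* **Aorta.** Each anatomical segment (ascending aorta through iliac, plus
  coronary, brachiocephalic/right-subclavian, left subclavian and renal
  branches) is subdivided into ~10 mm compartments forming an R-L-C ladder:
  compliance `C = A l / (rho c^2)` (Bramwell-Hill), inertance
  `L = rho l / A`, Poiseuille resistance `R = 8 mu l / (pi r^4)`. The
  ladder supports finite wave-transit times, so foot-to-foot pulse wave
  velocity is meaningful. Branches attach at segment junctions; terminal
  segments end in outlet units.
* **Viscoelastic wall.** The printed wave speed and the statically measured
  compliance of an elastomer aorta are mutually inconsistent under
  Bramwell-Hill for this geometry: at 12.6 m/s the tube itself stores only
  ~0.13 mL/mmHg, an order of magnitude below a static compliance of
  1.51 mL/mmHg. A lossy elastomer reconciles the two through creep, and the
  default `match = "distribute"` mode models exactly that: each compartment
  keeps its fast, wave-speed-true elastic compliance and additionally owns
  a slow creep compliance (the static deficit, shared in proportion to the
  elastic compliance) behind a relaxation resistance with a common time
  constant `wall_relaxation_time` (default 50 ms). Wave fronts then travel
  at the configured speed while the sealed system statically exhibits the
  full configured compliance. The creep branch is also the dominant damper
  of the tube's standing-wave modes, which in a purely elastic network
  would ring unphysically through diastole. Two alternative modes are kept
  for reference: `match = "ac"` rescales the elastic compliances to the
  static target (reporting the lowered effective wave speed), and
  `match = "pwv"` keeps the purely elastic, wave-speed-true tube.
* **Stiffness taper.** The local wave speed rises linearly with centerline
  position from a compliant root to a stiff distal aorta
  (`stiffness_taper` = distal/root ratio, default 3), normalized so that
  the end-to-end transit time equals `L / target_pwv` - the foot-to-foot
  measurement is taper-invariant to first order. The taper lowers the
  root's characteristic impedance `rho c / A` (taming the early-systolic
  pressure spike driven by peak ejection flow) and creates the distributed
  positive reflections that amplify the pulse downstream, the behavior
  observed at a distal abdominal measurement site.
* **Outlet units.** Each terminal branch carries a syringe compliance
  behind a port resistance proportional to the branch's characteristic
  impedance (`port_resistance_scale`, default 4) and a clamp resistance
  (default 4 mmHg s/mL per branch) into the first air chamber. Tightening
  every clamp by a common factor (`outlet_resistance_scale` >= 1) is the
  model of the rig's peripheral-resistance intervention.
* **Chambers, reservoir, atrium.** Chamber compliances 0.25 mL/mmHg each,
  joined by 0.15 mmHg s/mL, draining through 0.1 mmHg s/mL into the
  reservoir. The reservoir has a finite hydraulic compliance (4 mL/mmHg,
  a standpipe-like column) with base pressure `rho g venous_head`; the
  finite compliance is essential, because it is the redistribution of
  volume between the arterial and venous sides that raises atrial pressure
  and LVEDP when cardiac output falls. The atrium is a single passive
  compartment (10 mL/mmHg, no active kick).

Integration proceeds cycle by cycle until the cycle-to-cycle maximum
absolute pressure difference across all monitored nodes falls below
`convergence_tol` (0.5 mmHg, cap 50 cycles), after which a clean
post-convergence window (enough cycles for at least ~2.5 s) is recorded at
`output_fs` (1 kHz). Because every flow enters one compartment and leaves
another, total volume is conserved to round-off by construction; the
recorded drift is ~1e-15 relative. Two runs with the same configuration are
bit-identical.

## What the generator emulates, and what it does not

The defaults place the baseline (75 bpm, mid-grade aorta: 12.6 m/s,
1.51 mL/mmHg) at a cardiac output of 5.0 L/min, ascending pressures of
132/75 mmHg, LVEDP ~6 mmHg, a dicrotic notch at aortic valve closure,
near-zero diastolic aortic flow, and downstream pulse-pressure
amplification of ~1.2. The preset grid reproduces the standard sign
findings: higher heart rate lowers pulse pressure at matched output;
stiffer aortas raise it monotonically across all eight grades; clamping
the outlets raises mean pressure while cardiac output falls (the pump is
not a flow source); reduced output backs volume up venously and raises
atrial pressure and LVEDP; preload moves LVEDP; higher contractility
steepens the aortic upstroke.

Limits worth knowing before extrapolating to real recordings:

* The simulated ascending beat peaks early (the reflected wave arrives
  after the systolic peak), so the augmentation index is typically flagged
  undefined rather than reported - a type-C-like morphology. Recordings
  with late-systolic augmentation exercise that code path; the test suite
  covers it with constructed beats.
* The baseline pulse pressure (~58 mmHg) is wider than a textbook 40 mmHg:
  a lumped ladder with a handful of discrete reflection sites cannot fully
  reproduce the smooth impedance matching of a continuously tapering
  arterial tree.
* Foot-to-foot wave speed measured on the full branched, viscoelastic
  network reads ~30% below the configured front speed, because branch
  junctions and wall creep disperse the foot; the estimator itself is
  unbiased, which the suite shows on constructed delays (exact to one
  sample) and on an elastic, untapered, matched-termination straight
  ladder (within 10% of the configured speed).
* No non-Newtonian rheology, no 3D flow features, no active atrial kick,
  and no autonomic regulation: interventions change one knob at a time,
  which is the point of a rig-style model.

## Numerical and estimator choices

* **Units.** SI internally (Pa, m^3, s); mmHg, mL, L/min, bpm at every
  interface; 1 mmHg = 133.322 Pa.
* **Initialization.** Arterial nodes are primed at a configurable pressure
  (default 94 mmHg), chambers at their much lower steady-state fractions,
  the atrium and reservoir at the venous head, and the ventricle at its
  diastolic equilibrium volume. Because the ventricle starts at
  end-diastolic volume - above its cycle mean - the reservoir is started
  short by the estimated surplus, so the operating-point preload is not
  biased by the choice of starting phase. Convergence from this prime
  typically takes ~10 cycles.
* **Filtering.** All derivative-based estimators (beat feet, dp/dt max,
  wave-intensity derivatives, the curvature used for the augmentation
  inflection) use central differences after a zero-phase 4th-order
  Butterworth low-pass at 25 Hz, with odd-reflection padding so filter
  transients never corrupt boundary derivatives.
* **Beat feet.** Intersecting-tangent rule: the tangent at the point of
  maximal upstroke slope intersected with the horizontal through the
  preceding minimum. The minimum is taken as a low (2%) quantile of the
  smoothed window, which resists the downward bias a plain minimum
  acquires from residual noise over a long diastole. Beats whose spacing
  deviates more than 20% from the median are excluded from ensemble
  statistics.
* **LVEDP.** On a gradually accelerating isovolumic rise the raw tangent
  intersection lands a few tens of milliseconds into the upstroke and
  overreads the end-diastolic level; `lvedp_extract()` therefore walks
  back from the max-slope point to the last 5%-slope crossing and reads
  the pressure there. On a plateau-then-rise trace this reproduces the
  plateau exactly.
* **Augmentation.** The inflection pressure is the last negative-to-
  positive zero crossing of the smoothed second derivative between foot
  and systolic peak (the take-off of the reflected wave); a beat with no
  such crossing is flagged undefined, never invented.
* **Impedance.** Discrete Fourier harmonics 0..15 of one (preferably
  ensemble-averaged) beat; harmonic 0 is mean pressure over mean flow, and
  harmonics with negligible flow power are flagged unreliable rather than
  dropped. Phases are wrapped to (-pi, pi].
* **Wave intensity.** The default time-normalized convention
  `dI = (dP/dt)(dU/dt)` is sampling-rate invariant (mmHg m s^-3); the
  literal per-sample convention `dI_i = (P_{i+1}-P_i)(U_{i+1}-U_i)` is
  retained and equals the former divided by `fs^2` away from filter edges.
  Peak labeling: Wf1 is the largest positive peak in the first half of the
  trace, Wb the most negative excursion after it, Wf2 the largest positive
  peak after Wb; absent peaks are reported absent.
* **Foot-to-foot wave speed.** Median per-beat transit between matched
  proximal/distal feet (robust to a single mis-detected foot), fractional
  (sub-sample) foot times, error if the transit falls below one sample.
* **TPR convention.** `MAP / CO` with venous pressure neglected - the
  convention that makes the clinical arithmetic exact (94.25 / 5 = 18.85).
  Against the configured circuit resistance this overreads by the venous
  fraction (~7-9% at baseline), which is logged, not hidden.
* **Measurement taps.** "6 cm from the aortic root" and "23 cm beyond the
  arch center" are cumulative centerline distances; the containing
  compartment is chosen deterministically (round down).

## Problem sizes

The shipped tests and the acceptance script run the full branched ladder
(~85 compartments, ~270 state variables) to periodic steady state in under
half a second per scenario; the complete preset sweep plus all property
suites finishes in well under a minute on one CPU.
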