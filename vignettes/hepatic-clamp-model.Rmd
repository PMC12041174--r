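---
title: "A lumped-parameter model of hepatic arterial inflow under surgical clamping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of hepatic arterial inflow under surgical clamping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaflow)
```

## The model

`hepaflow` treats the supramesocolic arterial tree as a zero-dimensional
resistance network. Each vessel segment of radius $r$ (mm) and length $L$
(mm) carries a Hagen–Poiseuille resistance

$$R_\text{seg} = \frac{8 \mu L}{\pi r^4},$$

converted from SI to mmHg·min/ml (division by $133.322 \times 6\times10^7$).
Each peripheral bed is a two-parameter Windkessel outlet with resistance
$R$ and compliance $C$; under steady flow the compliance is inert, so an
outlet reduces to a resistor draining to a reference (venous) pressure.
The aortic inlet is a fixed pressure node at 100 mmHg. Steady branch flows
and nodal pressures are the solution of the Kirchhoff conservation
equations, assembled as a small dense linear system and solved directly —
there is no iterative tolerance to tune and identical inputs give
bit-identical output. Clamping a vessel removes its unknown from the
system, so a clamped segment carries *exactly* zero flow rather than a
large-resistance approximation; this matters for conditioning and for
reproducibility of the reversal sign tests.

Assumptions inherited from this formulation: laminar, fully developed,
Newtonian, steady flow in straight rigid tubes; no curvature, tortuosity,
entrance or jet losses; beds respond linearly. The steady (non-pulsatile)
treatment mirrors the source methodology's own simplification of using
constant flows, and the single-segment pancreaticoduodenal arcade mirrors
its arcade simplification. Because outlet resistances are calibrated to
measured flows, absolute geometric accuracy is secondary: calibration
absorbs geometric error into the bed resistances, and only the flow
*redistribution* between branches is predicted.

## Topology

The Michels type I template is:

```
aorta (100 mmHg) ── CT ── celiac ──┬── SA ── splenic bed
                                   └── CHA ── bif ──┬── PHA ── hepatic bed
                                                    └── GDA ── gda_d ── IPDA bed
aorta ── SMA trunk ── sma_j ── SMA ── mesenteric bed
gda_d ── ARCADE ── sma_j
```

The arcade closes the celiac–mesenteric collateral loop: it is what makes
GDA reversal (hepatopetal collateral flow) possible after CHA clamping or
under celiac-trunk stenosis. The replaced-RHA variant adds an RHA segment
with its own bed at `sma_j`; the stenosis variant applies an area
reduction over a sub-length of the celiac trunk, modelled as a series
Poiseuille element with effective radius $r\sqrt{1-a}$ (an effective-lumen
reduction, not a 3D jet — consistent with the reduced-order scope).

Sign convention: flow is positive along each segment's proximal→distal
orientation. The GDA is oriented bifurcation→arcade, so collateral flow
toward the liver appears as a negative GDA flow.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Inlet pressure | 100 | mmHg | standard mean aortic pressure; flow ratios are insensitive to proportional rescaling because calibration rescales resistances |
| Blood viscosity $\mu$ | 0.0035 | Pa·s | standard whole-blood value; affects only the (calibrated-away) absolute level |
| Outlet reference pressure | 0 | mmHg | only pressure differences matter; calibration absorbs the offset |
| Calibration tolerance | 0.01 | fraction | the intraoperative calibration criterion (<1%), negligible against 10–15% probe error |
| Interval variability $v$ | 0.15 | fraction | upper bound of the stated probe error margin; the one fully worked clinical interval (67 ml/min → 56.95–77.05) uses 15% |
| HABR gain | 0 | fraction | physics-only prediction; the conservative minimum (see below) |
| Reversal dead-band | 1 | ml/min | suppresses sign flapping of numerically tiny flows |

Template geometry (radii 1.2–3.5 mm, lengths 25–50 mm) is nominal: no
per-patient geometry is shipped, so these are typical supramesocolic
calibres, overridable per segment. The arcade default radius (1.2 mm) is
deliberately at the narrow end — the collateral arcade is a small-calibre
anastomotic route, and its resistance sets how much the post-CHA-clamp PHA
flow falls below baseline.

## Calibration

Outlet resistances are tuned by a damped multiplicative fixed point: each
measured branch's controlling outlet resistance is multiplied by
$(Q_\text{sim}/Q_\text{target})^{1/2}$ per iteration (damping 0.5, at most
200 iterations) until all mismatches fall within tolerance. This rule is
derivative-free and monotone for resistive networks; if a perturbed start
transiently reverses a collateral branch, the factor is replaced by a
corrective 0.5 or 2 toward the target's sign. Joint infeasibility (targets
that no positive bed resistance can meet under the fixed inlet pressure)
is detected when a resistance leaves $[10^{-9}, 10^{9}]$ mmHg·min/ml.

When CHA and GDA are both measured, the PHA outlet is tuned to the
*inferred* baseline $PHA_0 = CHA - GDA$ (conservation at the bifurcation);
a directly measured PHA value is kept for validation rather than tuning,
mirroring the clinical workflow in which $PHA_0$ is inferred. Unmeasured
beds (splenic, SMA) keep template defaults. Compliance is not calibrated:
it is unidentifiable under steady flow. Each clamp scenario's measurements
are *never* fed back into calibration — clamp predictions are pure
out-of-sample physics.

## Prediction intervals and the HABR correction

A point prediction $Q$ is reported with the symmetric probe-variability
interval $(|Q|(1-v), |Q|(1+v))$, sign preserved. The clinical tables'
printed ranges are not exactly ±15% of the printed predictions and their
construction is undocumented; the symmetric interval is therefore the
implementable contract, anchored to the one fully worked case
(67 ml/min at 15% → 56.95–77.05 ml/min), which it reproduces exactly.

Measured post-clamp PHA flows systematically exceed what passive
redistribution predicts. The accepted physiological explanation is the
hepatic arterial buffer response (HABR): clamping the GDA reduces
pancreaticoduodenal, hence portal, inflow, and the liver compensates by
dilating its arterial bed. `habr_adjust()` models this as a conductance
boost — the PHA outlet resistance is divided by $1+g$ — applied to clamp
scenarios only. The functional form is a package choice (the mechanism
fixes only the direction); the default $g = 0$ keeps the physics-only
prediction as the conservative lower bound, which is the clinically
relevant quantity: if the *minimum* expected flow is adequate, the real
flow will be too.

## The synthetic-patient generator

The generator replaces CT segmentations and intraoperative measurements so
that every pipeline stage is testable without patient data. Per patient
(all draws behind one integer seed, no global RNG state):

* geometry jitter: template radii × U(0.9, 1.1), lengths × U(0.85, 1.15);
* baseline targets inside the cohort's observed ranges: CHA ∈ U(150, 330),
  GDA ∈ U(18, 67) ml/min (PHA follows by conservation); RHA ∈ U(50, 75)
  ml/min for the replaced-RHA variant;
* ground-truth bed resistances: the jittered template calibrated tightly
  (tolerance $10^{-6}$) to those targets; unmeasured beds keep defaults;
* a true biological HABR gain drawn U(0.05, 0.35) and applied to the truth
  network's clamp scenarios, so synthetic "real" post-clamp PHA flows
  exceed the physics-only prediction — encoding the observed regularity as
  a testable statement;
* probe noise: multiplicative, mean 1, sd $v/1.96$ truncated at $\pm 3v$
  (default $v = 0.12$), so ~95% of draws fall within the stated 10–15%
  probe margin; the margin is stated clinically, the distribution is a
  package choice;
* for the stenosis variant, the drawn stenosis is applied to the celiac
  trunk *after* bed calibration, together with collateral remodelling
  (arcade radius ×1.5, GDA radius ×1.3) as described for such patients
  (arcade hypertrophy, enlarged GDA section); severe stenosis
  (area reduction ≥ 0.8) then reverses baseline GDA flow for every seed.

What the generator does *not* emulate: real anatomical tortuosity and
taper, non-Newtonian and pulsatile effects, measurement drift, patient
covariates, or any between-branch correlation structure beyond
conservation. Tests passing on synthetic cohorts therefore demonstrate
internal consistency of the method — calibration identifiability, correct
redistribution directions, safety of the interval lower bound under the
encoded HABR — not clinical accuracy on real patients.

## Numerical choices and degenerate inputs

* Direct dense `solve()` on systems of at most ~10 unknowns; residual
  (maximum nodal imbalance) is reported on every solution and is at
  machine level (`< 1e-9` relative).
* Clamping that disconnects part of the network is handled by solving the
  inlet's component; disconnected nodes get `NA` pressure and zero flows.
  A fully clamped inlet raises `no_open_path`.
* A zero flow target is rejected (`infeasible_targets`): it would need an
  infinite bed resistance.
* Baseline measurements with GDA > CHA are rejected as
  `nonphysical_baseline` for antegrade anatomy, with a pointer to the
  stenosis pathway (where a *negative* GDA measurement is legitimate and
  $PHA_0 = CHA - GDA$ still applies).
* Printed-table reproduction uses half-away-from-zero rounding
  (`round_half_up()`), matching how the tables' percentages were printed;
  rows whose printed errors are internally inconsistent with the stated
  error formula are flagged in the fixture and excluded from exact
  reproduction checks (they still count toward range-membership
  accuracy).

## Problem sizes used in the shipped tests

The property suites run on seeded synthetic cohorts of 200 patients for
the qualitative redistribution and safety properties, 50 patients for
calibration recovery, and exhaustive random trees up to 8 segments for
the series–parallel oracle; these sizes give stable proportions (a 95%
safety criterion on 200 patients resolves single failures) while keeping
the whole suite around a minute on one core.

## Known limitations

* Poiseuille resistances underestimate 3D losses (curvature, branching,
  entrance effects); after calibration this biases the *redistribution*
  magnitudes (e.g. the predicted PHA rise after GDA clamping is smaller
  than clinically reported), though the directions are robust.
* The HABR correction is directional, not mechanistic: it cannot predict
  the gain, only explore its effect.
* The arcade is one equivalent segment; patients with complex or
  duplicated arcades are outside the template's fidelity.
* Cirrhotic liver resistance and portal dynamics are not modelled.
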