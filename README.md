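# hepaflow

Reduced-order haemodynamic modelling of the hepatic arterial supply for
surgical clamp planning.

## The problem

Pancreaticoduodenectomy requires ligating the gastroduodenal artery (GDA),
the main communication between the celiac and superior mesenteric arterial
systems. Whether the liver will still receive adequate arterial inflow
through the proper hepatic artery (PHA) after ligation — especially in
patients with celiac-trunk stenosis or anatomical variants — is hard to
judge from imaging alone. `hepaflow` addresses this with a patient-specific
lumped-parameter model: each artery segment is a Hagen–Poiseuille resistor
(`R = 8μL/πr⁴`, converted to mmHg·min/ml), each peripheral bed a
two-parameter Windkessel outlet (resistive under steady flow), and the
aortic inlet a fixed 100 mmHg pressure source. Steady branch flows follow
from Kirchhoff conservation on the resulting resistance network; clamping
is an exact zero-flow constraint.

The intended users are researchers in computational haemodynamics and
surgical planning who want a transparent, fully scriptable counterpart to
3D CFD pipelines: outlet resistances are calibrated to intraoperative
transit-time flow measurements (to within 1%, far below the 10–15% probe
error), and the calibrated model predicts PHA flow after GDA or common
hepatic artery (CHA) clamping, with symmetric probe-variability intervals
`Q(1 ± v)` around each prediction.

## What the package provides

* `build_template()` — Michels type I anatomy, replaced right hepatic
  artery (Michels VIII), and celiac-trunk stenosis templates, with a
  single-segment pancreaticoduodenal arcade closing the celiac–mesenteric
  collateral loop.
* `solve_steady()`, `clamp_segment()`, `windkessel_waveform()` — the
  steady network solver and a single-outlet pulsatile demonstrator.
* `calibrate_outlets()`, `infer_pha0()` — outlet-resistance calibration to
  measured CHA/GDA flows and baseline PHA inference (`PHA0 = CHA − GDA`).
* `run_scenario()`, `predict_scenarios()`, `predict_interval()`,
  `habr_adjust()`, `detect_reversal()` — clamp-scenario predictions,
  intervals, an optional hepatic-arterial-buffer-response correction, and
  flow-reversal detection.
* `relative_error()`, `rel_error_of_min()`, `range_accuracy()`,
  `load_validation_tables()` — the validation statistics and the embedded
  ten-row clinical validation tables.
* `generate_patient()`, `generate_cohort()` — a seedable synthetic-patient
  generator (geometry jitter, cohort-range flow targets, probe noise,
  biological HABR in the ground truth) so the full pipeline is testable
  without any patient data.
* `run_pipeline()`, `read_network()`, `read_measurements()` plus a thin
  CLI (`inst/scripts/hepaflow.R`) tying the stages together.

## Worked example

Calibrate the normal-anatomy template to measured baseline flows of
331 ml/min (CHA) and 60 ml/min (GDA), then predict both clamp scenarios:

```r
library(hepaflow)
net  <- build_template("MICHELS_I")
meas <- data.frame(branch = c("CHA", "GDA"), flow = c(331, 60))
cal  <- calibrate_outlets(net, meas)
cal$report
#> <calibration_report> converged after 7 iterations (tolerance 0.01 )
#>   per-branch relative mismatch:
#>      GDA      PHA      CHA
#> 0.005177 0.004503 0.004625
predict_scenarios(cal$network, variability = 0.15)
#>   scenario branch predicted_flow interval_min interval_max variability_used reversed
#>   baseline    CHA         329.47       280.05       378.89             0.15    FALSE
#>   baseline    PHA         269.78       229.31       310.25             0.15    FALSE
#>   baseline    GDA          59.69        50.74        68.64             0.15    FALSE
#>  clamp_GDA    CHA         270.09       229.58       310.60             0.15    FALSE
#>  clamp_GDA    PHA         270.09       229.58       310.60             0.15    FALSE
#>  clamp_GDA    GDA           0.00         0.00         0.00             0.15    FALSE
#>  clamp_CHA    CHA           0.00         0.00         0.00             0.15    FALSE
#>  clamp_CHA    PHA         245.58       208.74       282.41             0.15    FALSE
#>  clamp_CHA    GDA        -245.58      -282.41      -208.74             0.15     TRUE
```

Reading this: calibration reproduces the measured baseline within 0.6% on
every branch and pins the inferred baseline PHA at ~270 ml/min
(331 − 60 = 271, by conservation at the GDA bifurcation). Clamping the GDA
reroutes its share into the PHA (269.8 → 270.1 ml/min here; the common
trunk pressure drop is small in this template) while CHA inflow falls.
Clamping the CHA reverses the GDA (negative sign: flow runs from the
mesenteric side through the pancreaticoduodenal arcade toward the liver),
and the PHA is then fed entirely by that collateral route. Each prediction
carries its ±15% probe-variability interval; the lower bound is the
clinically relevant minimum expected liver inflow.

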