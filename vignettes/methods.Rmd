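---
title: "Methods: per-breath respiratory mechanics and PEEP titration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-breath respiratory mechanics and PEEP titration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventmech)
```

## The estimation problem

A ventilated patient's airway pressure `Paw` and flow `Q` are sampled at a
fixed rate (default 50 Hz). Under the linear single-compartment model of the
respiratory system, during inspiration

```
Paw(t) = Ers * V(t) + Rrs * Q(t) + P0
```

with `Ers` the respiratory-system elastance (cmH2O/L), `Rrs` the resistance
(cmH2O·s/L), `P0` a fitted offset pressure (cmH2O), and `V(t)` the inspired
volume, the running integral of flow from the start of the breath. The three
parameters are identified per breath by ordinary least squares on the
inspiratory samples only — expiration is passive and valve-shaped, so it
carries no extra information about the patient under volume control.

`fit_single_compartment()` solves the least-squares problem through a QR
decomposition and reports coefficient standard errors, residual sigma, R²
and the condition number of the regressor matrix `[V, Q, 1]`. Units matter:
streams carry flow in L/min (ventilator convention) and the parser converts
to L/s internally, so elastance and resistance come out in the clinical
units above.

### Why inspiration must carry flow variation

With a constant (square) inspiratory flow, `Q(t)` is collinear with the
intercept and `V(t)` is collinear with time: the regressor matrix becomes
ill-conditioned and `Rrs`/`P0` are not separately identifiable. The fit is
then still reported (the estimates are the minimum-norm solution) but
flagged `ill_conditioned`, and the breath's Stiffness is left undefined so
it cannot contaminate downstream medians. The descending-ramp profile of
volume-control ventilation — peak flow `2·VT / T_insp` decaying linearly to
zero — identifies all three parameters exactly from noiseless data.

## Time-varying elastance and the Stiffness metric

Within one inspiration, after removing the resistive and offset components,
the point-wise ("dynamic") elastance is

```
Edrs(tau) = (Paw - Rrs * Q - P0) / V,    tau = t / T_insp in (0, 1]
```

Samples whose volume is below 5 % of the end-inspiratory volume
(`volume_floor_fraction`) are excluded: near the start of the breath `V` is
tiny and the ratio is numerically meaningless. For a truly linear lung
`Edrs` is flat at `Ers`; curvature reveals intra-breath nonlinearity
(recruitment, overdistension) and spontaneous effort carves a mid-breath
trough.

The per-breath summary, **Stiffness**, is the trapezoidal area under
`Edrs(tau)` divided by the tau-span the curve covers. Normalising by the
covered span (rather than assuming `[0, 1]`) keeps the metric equal to the
generating `Ers` for a constant curve regardless of the volume-floor cutoff,
and normalising time by `T_insp` makes breaths at different respiratory
rates directly comparable. Negative Stiffness is reported as-is — it is the
canonical signature of strong spontaneous effort and is diagnostic, not an
error.

A rolling mean over the most recent `window` *defined* values (default 60
breathing cycles, roughly "a few minutes" at adult rates) gives the smoothed
trend; quarantined breaths are skipped, not zero-filled.

## Quarantine filtering

Real captures contain artifacts — suction, disconnections, coughs, serial
glitches. Each breathing cycle is screened in a documented, fixed order, and
the first failing rule names the reason:

1. `no_markers` — the cycle lacks its `BS` or `BE` marker;
2. `pressure_jump` — any sample-to-sample pressure step > 10 cmH2O;
3. `flow_jump` — any flow step > 10 L/min (native stream units);
4. `too_short` — fewer than 5 samples;
5. `parse_corrupt` — a malformed data line inside the cycle;
6. `no_flow_reversal` — no positive-to-negative flow transition, so the
   inspiration/expiration split is undefined.

Quarantined breaths keep their rows with NA mechanics and the reason code:
the output always has exactly one row per detected cycle, and counts per
reason are part of the pipeline's diagnostics. Inspiration ends at the last
sample before the first strictly negative flow following positive flow;
zero-flow samples (an inspiratory pause) remain inspiratory.

## PEEP detection, calibration, and manoeuvre titration

Detected PEEP is the median pressure over the last 20 % of each expiration
(at least 3 expiratory samples required). When the ventilator's displayed
PEEP differs from the measured value, `calibrate_peep()` establishes the
constant offset `displayed - measured`; offsets beyond 5 cmH2O are applied
but flagged as probable mis-entries.

During a step-wise recruitment manoeuvre, accepted breaths are snapped to
the nearest half-step PEEP level, contiguous runs are identified, and runs
up to and including the first maximum-level run form the ascending arm. Each
(level, arm) cell is summarised by the **median** Stiffness — robust to the
occasional residual artifact — and cells with fewer than 3 breaths are
dropped. On the descending arm the minimal-Stiffness level is located (ties
resolve toward the higher, recruitment-preserving PEEP) and the
recommendation is the descending level **one protocol step above** the
minimum; at the boundary the minimum itself is recommended with a warning.
The signed trapezoidal area between ascending and descending curves over
their common PEEP range quantifies hysteresis: positive area means the lung
was softer on the way down, i.e. the manoeuvre recruited. The decision field
of every report is `"pending"` — acceptance or override belongs to the
clinician.

## The synthetic lung

No public data exist in this capture dialect, so the package's only data
source is its simulator, which is deliberately explicit about its laws:

* **Inspiration.** Ramp flow `Q(t) = Qpeak (1 - t/T_insp)` with
  `Qpeak = 2 VT / T_insp` (or square flow), analytic inspired volume, and
  pressure from the model equation at the effective elastance.
* **Elastance law.** `Ers(PEEP) = ers_base + curvature (PEEP - peep_opt)^2`,
  the U-shape of derecruitment below and overdistension above the optimum;
  on the descending arm of a manoeuvre the elastance is multiplied by
  `recruit_factor <= 1`, which is what produces Stiffness–PEEP hysteresis.
* **Expiration.** Passive decay with time constant `Rrs/Ers`, modulated by
  an exhalation-valve opening transient (time constant 0.4 s) so pressure
  and flow leave end-inspiration smoothly. A real exhalation valve opens
  over a finite time; an idealised instantaneous opening would make every
  clean breath step ~12 cmH2O and ~90 L/min in one sample — indistinguishable
  from the artifacts the quarantine filters exist to catch. The closed form
  used is the exact solution of `dV/dt = -(V/tau)(1 - exp(-t/tau_open))`.
  Note the same reasoning explains why *pure square* flow trips the
  flow-jump filter at default thresholds: its end-inspiratory step is
  genuine.
* **Effort.** With per-breath probability `effort_prob`, a half-sine
  pressure dip of amplitude `effort_amp` spanning the middle 60 % of the
  inspiration is subtracted from `Paw` (under volume control the flow stays
  ventilator-imposed). Gaussian noise of SD `noise_sd` is added to every
  pressure sample.
* **Safety refusal.** Any manoeuvre whose predicted peak airway pressure
  exceeds 80 cmH2O is refused outright; the protocol builder stops its
  ascent at a 55-cmH2O peak by default.
* **Corruption injection.** `corrupt_stream()` damages chosen breaths so
  that exactly one quarantine rule fires each (marker deletion, ±12-unit
  spikes, truncation) and returns the injection log, enabling exact
  sensitivity/false-positive accounting.

Breaths tile the breathing period exactly (`60/resp_rate` seconds, one
sample short of the next breath's start), so the dialect's
cumulative-tick time reconstruction agrees with the simulator's own
timestamps.

## Design of the recovery study

The test suite measures how often the titration recovers "minimum + one
step" on a 14→26→14 cmH2O protocol with 5 breaths per level and pressure
noise of 0.5 cmH2O. At that noise level the ramp's V–Q collinearity puts the
per-breath elastance SD near 2 cmH2O/L, so a shallow U (curvature
~0.15) is statistically unresolvable from 5-breath medians — not a pipeline
failure but a fact about the information in the data. The study therefore
uses the sharpest U the simulator can safely ventilate: baseline elastance
10 cmH2O/L and, per minimum position, curvature
`min((88 - 10) / dist_max^2, 1.5)` where `dist_max` is the farthest protocol
level — chosen so the largest on-protocol elastance stays at 88 cmH2O/L,
keeping predicted peak pressures (~70 cmH2O) inside the simulator's
80-cmH2O refusal. Under that scenario the recommendation is recovered in
96–100 % of seeded replicates per minimum position.

## Numerical choices and problem sizes

* Volume by `pracma::cumtrapz` — exact for piecewise-linear flow.
* OLS by QR with an SVD condition number; fits with condition above `1e8`
  are flagged rather than silently reported.
* Curve areas by `pracma::trapz`; arm comparison on the union PEEP grid via
  linear interpolation over the common range.
* Level and cell summaries by medians; PEEP by the expiratory-tail median.
* Default problem sizes in the tests — 1,000-breath corrupted streams,
  200-replicate recovery studies, 200-breath noisy-estimation sessions —
  are package choices sized to give tight Monte-Carlo margins while keeping
  each property check around the two-minute mark on one CPU.

## Limitations

The model is linear and single-compartment: airway-opening pressure,
flow-dependent resistance, and viscoelastic stress relaxation are all
absorbed into the three constants or into `Edrs` curvature. Effort is
detected, not estimated — no esophageal-pressure surrogate is attempted.
The simulator's U-shaped elastance law and half-sine effort are test
constructions for validating the estimator and the titration logic; they
are not a patient model, and recommendations from this package are decision
*support*, gated behind an explicit clinician accept/override step.
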