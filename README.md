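# ventmech

Per-breath respiratory mechanics from ventilator waveform streams, with
recruitment-manoeuvre PEEP titration and a synthetic-lung simulator.

## What it does

Mechanically ventilated patients are monitored through the pressure and flow
waveforms their ventilator already produces. `ventmech` turns a raw waveform
capture into breath-by-breath estimates of respiratory mechanics:

1. **Stream parsing.** Captures are line-oriented text: `BS`/`BE` marker
   lines delimit breaths, data lines carry `<flow>,<pressure>` samples at a
   fixed rate (default 50 Hz, flow in L/min). Both batch
   (`parse_stream()`, `read_capture()`) and incremental (`stream_parser()`)
   parsers are provided and produce identical results for any chunking of
   the input.
2. **Quarantine filtering.** Each breathing cycle is screened in a fixed
   order — missing markers, sudden pressure steps (> 10 cmH2O),
   sudden flow steps (> 10 L/min), too few samples (< 5), corrupt data
   lines, and no inspiration→expiration flow reversal. Quarantined breaths
   keep their rows, labelled with a reason code, so nothing silently
   disappears.
3. **Single-compartment identification.** For each accepted inspiration,
   ordinary least squares of airway pressure on inspired volume and flow,

   `Paw(t) = Ers · V(t) + Rrs · Q(t) + P0`

   yields respiratory-system elastance `Ers` (cmH2O/L), resistance `Rrs`
   (cmH2O·s/L) and offset pressure `P0` (cmH2O). Volume is the trapezoidal
   integral of flow, exact for the ramp flow profile of volume-control
   ventilation.
4. **Time-varying elastance and Stiffness.** Within the inspiration the
   point-wise elastance `Edrs(τ) = (Paw − Rrs·Q − P0) / V` is evaluated on
   normalised inspiratory time τ ∈ (0, 1] (samples below 5 % of the
   end-inspiratory volume are dropped to avoid the V → 0 singularity). The
   per-breath **Stiffness** is the trapezoidal area under this curve divided
   by the τ-span it covers, which makes it equal to `Ers` for a linear lung
   and comparable across respiratory rates. Strong spontaneous effort
   genuinely drives Stiffness negative; that signature is preserved, not
   clipped.
5. **PEEP detection and calibration.** PEEP is the median airway pressure
   over the last 20 % of each expiration; an optional displayed-vs-measured
   calibration (`calibrate_peep()`) moves it onto the ventilator-display
   scale, warning when the offset exceeds 5 cmH2O.
6. **Recruitment-manoeuvre titration.** During a step-wise PEEP manoeuvre
   (e.g. 14 → 26 → 14 cmH2O in 2-cmH2O steps) breaths are snapped to
   protocol levels and split into ascending/descending arms at the top
   level. The recommended PEEP is the descending-arm level **one protocol
   step above** the minimal-Stiffness level (ties resolve toward higher
   PEEP), balancing recruitment against overdistension; the
   ascending-minus-descending hysteresis area quantifies recruitment. The
   result always carries an explicit *pending clinician accept/override*
   decision field — the package recommends, the clinician decides.

Because no public waveform data exist for this capture dialect, the package
ships a physiologically explicit simulator (`lung_config()`,
`vent_settings()`, `simulate_session()`, `simulate_rm_session()`,
`corrupt_stream()`) that generates dialect-conformant streams with known
ground truth: U-shaped `Ers(PEEP)` laws, descending-arm recruitment,
spontaneous-effort artifacts, Gaussian pressure noise, and targeted stream
corruptions for testing the quarantine filters. See the methods vignette
(`vignettes/methods.Rmd`) for model details and limitations.

## Worked example

Simulate a recruitment manoeuvre on a lung whose elastance minimum sits at
PEEP 18 cmH2O, then run the full offline pipeline:

```r
library(ventmech)

lung <- lung_config(peep_opt = 18, curvature = 0.6, recruit_factor = 0.85,
                    noise_sd = 0.3, seed = 42)
vent <- vent_settings(tidal_volume = 0.5, resp_rate = 15)
sim <- simulate_rm_session(lung, vent, breaths_per_level = 6)

res <- run_offline(sim$text, rm = TRUE)
dplyr::select(res$results, breath_index, status, ers, rrs, p0, stiffness, peep)
#> # A tibble: 66 × 7
#>   breath_index status     ers   rrs    p0 stiffness  peep
#>          <int> <chr>    <dbl> <dbl> <dbl>     <dbl> <dbl>
#> 1            1 accepted  35.5  8.78  13.3      35.3  14.0
#> 2            2 accepted  34.3  7.77  14.2      34.1  14.1
#> 3            3 accepted  35.9  8.61  13.2      36.0  14.0
#> 4            4 accepted  35.5  8.64  13.4      35.3  14.0
#> 5            5 accepted  33.5  7.75  14.5      33.4  14.0
#> # ℹ 61 more rows

res$rm
#> <rm_result> recruitment-manoeuvre PEEP titration
#>   minimal-stiffness PEEP (descending arm): 18 cmH2O
#>   recommended PEEP:                        20 cmH2O
#>   hysteresis area (ascending - descending): 35.6 cmH2O
#>   decision: pending clinician accept/override
```

The titration lands exactly one step above the generating minimum. Results
follow tidyverse conventions throughout: `tidy()`, `glance()` and
`augment()` work on fits and manoeuvre results, `ggplot2::autoplot()` draws
the Stiffness trend and the PEEP ladder, and `run_offline(..., output_dir =
...)` writes the breath table (CSV and JSON-lines), the Edrs curves, and the
manoeuvre report.

The same pipeline is scriptable from the shell:

```sh
exec/ventmech simulate --out sim --rm --seed 5 --peep-opt 18 --curvature 0.6
exec/ventmech rm-report --input sim/capture.txt --out results
```

## Limitations

The estimator is the linear single-compartment model; nonlinear or
over-distended mechanics show up as curvature in `Edrs(τ)` rather than being
modelled explicitly. Spontaneous effort is detected only through its
Stiffness signature (inflated variance, negative values), not separated from
passive mechanics. The simulator is a test harness, not a patient model:
see the vignette for the exact waveform laws and their deliberate
simplifications.
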