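---
title: "Inspired-CO2 targeting by flow-proportional admixture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inspired-CO2 targeting by flow-proportional admixture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2challenge)
```

## The problem

Cerebrovascular-reactivity (CVR) imaging needs a controlled hypercapnic
stimulus: the fraction of CO2 in the inspired gas (FCO2i) is driven
through a known waveform while blood-flow responses are recorded. The
classical delivery approach premixes O2/CO2/N2 into a reservoir the
subject breathes from; it does not transfer to mechanical ventilation,
where one-way valves isolate the inspiratory limb. The admixture
("additional CO2") approach instead measures the respiratory gas flow and
injects a proportional stream of concentrated CO2 into the inspiratory
limb, so it works identically for a ventilator and for a spontaneously
breathing subject wearing a mask.

This package implements that method end to end in software: the stimulus
protocol engine, the proportional controller, a closed-loop respiratory
simulator that stands in for the bench and subject experiments, and the
breath-by-breath analysis that quantifies how accurately the target was
met.

## Controller model

Mixing a respiratory stream (flow $\dot M_{res}$, CO2 fraction
$F_{CO_2,res}$) with an additional stream (flow $\dot M_{add}$, fraction
$F_{CO_2,add}$) and solving the mass balance for the target inspired
fraction $F_{CO_2,i}$ gives the admixture ratio

$$\frac{\dot M_{add}}{\dot M_{res}}
  = \frac{F_{CO_2,i}-F_{CO_2,res}}{F_{CO_2,add}-F_{CO_2,i}},$$

implemented in `additional_flow_ratio()`. The mass-flow-controller
setpoint is this ratio times the measured flow (`setpoint_from_flow()`),
updated every simulator step. Because the additional gas carries no
oxygen, the inspired O2 is diluted to $F_{O_2,res}/(1+\dot M_{add}/\dot
M_{res})$ (`resulting_fo2i()`). Safety clamping (`clamp_target()`)
enforces a 5 % ceiling on inspired CO2 and a 19 % floor on inspired O2;
a conflict with the O2 floor is always resolved by lowering the CO2
target, never by adding O2, since the system has no O2 source. We clamp
and warn rather than refuse over-limit protocols, so a protocol file is
always runnable and the operator sees what was actually delivered.

Two delivery systems share this surface: `"additional"` (the admixture
controller above) and `"reservoir"`, a three-gas reference mixer
(`reservoir_setpoints()`) feeding a finite breathing reservoir.

## Alveolar gas exchange

With alveolar ventilation $\dot V_A$ (L/min), metabolic rates $\dot
V_{O_2}$ and $\dot V_{CO_2}$, and inspired fractions $F_{gas,i}$, the
steady-state alveolar fractions are

$$F_{O_2,A}=F_{O_2,i}-\dot V_{O_2}/\dot V_A,\qquad
  F_{CO_2,A}=F_{CO_2,i}+\dot V_{CO_2}/\dot V_A,$$

implemented in `steady_state_alveolar()`. The simulator integrates the
dynamic counterpart,

$$\frac{dF_A}{dt}=\frac{\dot V_A\,(F_i-F_A)\pm\dot V_{gas}}{FRC},$$

whose equilibrium is exactly the steady state above; the test suite
checks convergence to within $10^{-6}$ in fraction units. Partial
pressures are reported as $P = F\,(P_{atm}-P_{H_2O})$ with 760 and
47 mmHg (`to_partial_pressure()`); no humidity correction is applied
inside the loop — the conversion is a reporting step only.

## The stimulus protocol

`default_protocol()` builds the reference target function: 60 s baseline;
45 s boxes at 1, 3 and 5 % separated by 45 s baselines; a 60 s ramp from
0 to 5 %; a 45 s baseline; a 60 s half-sinusoid peaking at 5 % (half of a
120 s period); and a final 60 s baseline — 555 s in total. Segments are
half-open $[start, end)$ so the target is single-valued at joins, with
concentrations stored as fractions internally and percent in the JSON
files (one conversion, at I/O, avoids 100x unit mistakes at module
boundaries).

## What the simulator emulates

`simulate_closed_loop()` advances a fixed-step loop (default
$dt = 10$ ms):

* **Flow source.** Volume control delivers constant inspiratory flow
  $V_T/T_{insp}$; pressure control the exponential
  $(P_{insp}/R)\,e^{-\tau/RC}$, so its tidal volume depends only on
  pressure, time and compliance. The spontaneous subject breathes
  half-sinusoidal inspirations with a 40 % duty cycle; a linear
  chemoreflex scales the breathing rate by
  $\max(0,\,1+g_c\,(P_{CO_2,A}-P_{CO_2,A,0}))$ with $g_c$ in /kPa.
* **Controller.** The sensor reports $g\times$ the true respiratory flow;
  $g<1$ reproduces the under-reading of laminar flow by a sensor
  calibrated on more turbulent flow, and propagates to a delivered
  plateau of $r g/(1+r g)$ instead of the target $r/(1+r)$ — the
  mechanism behind the consistent ventilator-circuit undershoot.
* **Circuit transport.** The volume between the gas inlet and the
  sampling port is modeled as 1–3 well-mixed compartments in series
  (default 3), not full advection: this captures the slower
  concentration rise when the inlet sits near the flow sensor (humidifier
  plus tubing, 300 + 500 mL defaults) versus near the sampling port
  (50 mL port volume) with very few parameters. Compartment updates use
  the exact exponential solution for a well-mixed volume under
  piecewise-constant inflow, so integration is unconditionally stable;
  halving $dt$ moves delivered fractions by less than $10^{-4}$.
* **Lung.** A well-mixed series dead space (150 mL default) shapes the
  expiratory concentration rise seen by the analyzer; gas reaching the
  alveolar store (FRC 3000 mL) only counts after the dead space has been
  refilled, so the average fresh-gas delivery equals
  $f\,(V_T-V_D)$ exactly. Test-lung runs set
  $\dot V_{O_2}=\dot V_{CO_2}=0$, so expired gas equals inspired gas
  after washout.
* **Analyzer.** Sidestream sampling at 60 Hz with a 3 s transit delay and
  additive Gaussian noise on the percent readings (default SD 0.05
  percentage points — small against the 0.4 pp accuracy scale and
  plausible for a sidestream analyzer). One seeded generator per
  simulation makes traces bit-reproducible.
* **Reservoir arm.** The premixed gas is drawn from a 700 mL reservoir
  refilled at 8 L/min; when minute ventilation outstrips the fresh-gas
  flow the reservoir runs empty mid-inspiration and the subject draws
  room air, reproducing the characteristic late-inspiratory concentration
  decline of non-excessive fresh-gas flows.

Defaults for the subject are a resting adult: tidal volume 500 mL, rate
14 /min, dead space 150 mL, FRC 3000 mL, $\dot V_{O_2}=0.25$ and $\dot
V_{CO_2}=0.20$ L/min (respiratory quotient 0.8), chemoreflex gain
0.3 /kPa — a mid-range hypercapnic ventilatory response chosen once as a
plausible resting value, not fitted to anything.

The generator does **not** emulate: cardiogenic oscillations, analyzer
drift or water-trap artifacts, leaks and motion, irregular breathing,
airway mechanics beyond a single RC stage, or inter-subject variability
beyond the analyzer noise seed. Passing tests therefore demonstrate that
the pipeline recovers what this model family produces, not that it is
robust to every artifact of real recordings.

### Actuator cap

The mass-flow-controller setpoint is capped (default 5 L/min) so a
corrupt flow sample cannot command a runaway CO2 flow. The cap is chosen
above the ~3 L/min peak demanded during a 5 % box at chemoreflex-elevated
ventilation: an actuator that saturates inside the study conditions would
itself create a target undershoot, and the hardware this models is rated
well above these flows.

## Breath-by-breath analysis

`detect_breath_phases()` segments the CO2 trace by crossings of an
adaptive threshold (midpoint of a rolling min/max, ~8 s window), rejects
candidates shorter than 0.5 s or with excursions under 0.3 pp (analyzer
glitches sit below physiological breath scales), and, in spontaneous
mode, additionally requires an exponential-approach fit to the expiratory
rise with normalized RMSE below 0.25. The exact decay test used in the
original semi-automated workflow is not documented; this criterion is a
stand-in with the same intent. Phase boundaries are then refined: the
expiration is walked back to its rise onset, its end is the end of the
near-peak (end-tidal) plateau, and the next inspiration starts where the
post-plateau fall flattens — the fall transition belongs to neither
phase. That last rule is what keeps inspired values clean on reservoir
traces, where early-inspiratory gas is itself CO2-rich. Ventilated traces
that carry a flow channel are segmented on inspiratory flow instead: a
passive test lung expires gas of the composition it inspired, so at
steady plateaus its capnogram carries no breath structure at all.

`extract_breath_records()` reports inspired CO2/O2 peak and baseline over
the inspiration (trimmed 10 % per side against boundary contamination), a
tracked inspired value (whole inspiration for the admixture system; first
half only for reservoir traces, whose late decline reflects dead-space
gas that never reaches the alveoli), and end-tidal values as the median
of the final 100 ms of the expiratory plateau, which resists
single-sample noise. O2 is extracted with definitions symmetric to CO2.

`align_and_resample()` interpolates records onto a uniform grid;
ventilated-mode records are shifted by -8 s (3 s analyzer delay plus the
multiple-breath washout of the ventilator tubing), spontaneous records
are not shifted. `bin_and_aggregate()` bins values into 5 s bins and
bootstraps a 95 % CI across runs (seeded, 1000 resamples, so confidence
bands are exactly reproducible). Bins are labeled by their **left edge**
by default: with 5 s bins and a 3 s delay the label then sits within
half a second of the mean stimulus time of the binned samples, which is
precisely how coarse binning absorbs the sampling delay without an
explicit shift; center labeling would leave a residual 3 s misalignment
worth up to ~0.8 pp on the steepest half-sine slopes. End-tidal channels
are baseline-subtracted per run (mean over the first 60 s) before
aggregating.

`mean_target_deviation()` evaluates measured-minus-target per stimulus
window after transition removal (boxes lose their first 10 s and last
5 s; the ramp its last 5 s; half-sine and baselines are kept whole),
reporting both the signed mean and the mean absolute deviation — "mean
deviation" alone is ambiguous, and the conservative headline statistic is
the maximum mean absolute deviation across stimuli. Confidence intervals
are computed across runs when several are given, else across samples,
and the report records which.

## Numerical and degenerate-input choices

* Samples exactly on a window boundary belong to the later segment
  (matching the protocol's half-open segments).
* A box shorter than 15 s has no evaluation window and is flagged, never
  silently averaged.
* Empty aggregation bins are `NA` with `n = 0`, never zero.
* Flow at or below zero commands a zero setpoint (expiration phase).
* Alveolar fractions are clipped to $[0,1]$ with a warning; a non-finite
  simulator state aborts with a timestamp.
* Breath records within a run are timestamped at mid-inspiration.

## Problem sizes

The shipped test suite runs closed-loop simulations of 60–555 s at
$dt = 10$ ms and 60 Hz sampling, six-run aggregates for the
subject-configuration accuracy check, and 200–1000 bootstrap resamples;
these sizes were chosen so the full suite completes in well under a
minute on a single core while every check still exercises multiple
washout time constants and tens of breaths.

## Known limitations

* Deviations from this simulator quantify the pipeline against its own
  generative model; real analyzer artifacts and irregular breathing will
  lower breath-detection rates (detection already drops a few breaths
  where fast target rises make inspired and end-tidal concentrations
  nearly equal, which is physical, and concentrated in the removed
  transition windows).
* The reservoir arm at 8 L/min fresh gas undershoots high targets when
  chemoreflex-driven minute ventilation exceeds the fresh-gas flow, even
  with early-inspiration tracking; this mirrors the known flow-dependence
  of reservoir systems and is reported, not corrected.
* Only inspired-CO2 targeting is modeled: no end-tidal forcing or
  prospective targeting, no O2 co-administration, no pathology models,
  and no hardware drivers.
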