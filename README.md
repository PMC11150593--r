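# co2challenge

Tools for designing and evaluating inspired-CO2 gas challenges — the
controlled hypercapnic stimuli used in cerebrovascular-reactivity (CVR)
imaging — with a focus on the *flow-proportional admixture* delivery
method, which works both under mechanical ventilation and in spontaneous
breathing. The package is aimed at respiratory-physiology and
neuroimaging methods developers who need to prototype stimulus protocols,
study controller behavior, or validate breath-by-breath analysis
pipelines without bench hardware.

## The method

Instead of premixing the whole inspired gas in a reservoir, the admixture
method measures the respiratory gas flow and injects a proportional
stream of concentrated CO2 into the inspiratory limb. Solving the mixing
mass balance for a target inspired fraction `FCO2i` gives the flow ratio

    Madd / Mres = (FCO2i − FCO2res) / (FCO2add − FCO2i)

which, multiplied by the measured flow, is the mass-flow-controller
setpoint. Because the added gas is O2-free, inspired O2 falls to
`FO2res / (1 + Madd/Mres)`; safety limits clamp the delivered target to
at most 5 % CO2 and at least 19 % O2. Alveolar consequences follow the
steady-state gas equations `FO2A = FO2i − V̇O2/V̇A` and
`FCO2A = FCO2i + V̇CO2/V̇A`.

The package implements, as separate composable pieces:

* **Protocols** — piecewise target functions (baseline / box / ramp /
  half-sine) with JSON serialization and safety clamping
  (`default_protocol()`, `target_fco2i()`, `clamp_target()`).
* **Controller** — the admixture ratio and setpoints, plus a three-gas
  reservoir reference mixer (`additional_flow_ratio()`,
  `setpoint_from_flow()`, `reservoir_setpoints()`).
* **Closed-loop simulator** — ventilated test lung (volume or pressure
  control) or spontaneously breathing subject with a CO2 chemoreflex,
  circuit gas transport with configurable inlet placement, a dynamic
  alveolar compartment, and a delayed, noisy sidestream analyzer
  (`simulate_closed_loop()`).
* **Breath analysis** — breath-phase detection, inspired peak/baseline
  and end-tidal extraction, alignment, 5 s binning with bootstrap
  confidence intervals, partial-pressure conversion
  (`detect_breath_phases()`, `extract_breath_records()`,
  `bin_and_aggregate()`, `to_partial_pressure()`).
* **Metrics** — per-stimulus target deviations with transition removal
  and a pass/fail accuracy report (`stimulus_windows()`,
  `mean_target_deviation()`, `cmd_report()`).

See `vignettes/inspired-co2-targeting.Rmd` for the models, assumptions
and numerical choices.

## Worked example

Simulate one spontaneously breathing subject through the default 555 s
protocol, analyze the analyzer trace breath by breath, and score target
accuracy:

```r
library(co2challenge)

p <- default_protocol()
p
#> <stimulus_protocol> 'default': 11 segments, 555 s total
#>    1. baseline   60.0 s  level 0.0 %
#>    2. box        45.0 s  level 1.0 %
#>    ...
#>   10. half_sine  60.0 s  level 5.0 %
#>   11. baseline   60.0 s  level 0.0 %

sim <- simulate_closed_loop(p, subject_model(), circuit_config(),
                            controller_config(), seed = 1)
sim
#> <co2_sim> 555 s, 33300 analyzer samples at 60 Hz, 158 breaths, seed 1

ph  <- detect_breath_phases(sim$trace, "spontaneous")
rec <- extract_breath_records(sim$trace, ph, "additional")
agg <- bin_and_aggregate(data.frame(t_s = rec$t_s, value = rec$insp_co2),
                         seed = 1)
res <- cmd_report(agg, p)
#> Per-stimulus inspired-CO2 target deviation (percentage points)
#>  stimulus      kind level_percent  n mean_dev mean_abs_dev ...
#>         2       box             1  6    0.001        0.004
#>         4       box             3  6    0.006        0.006
#>         6       box             5  6    0.021        0.021
#>         8      ramp             5 11   -0.084        0.088
#>        10 half_sine             5 10    0.002        0.190
#>  ...
#> Overall max |deviation| across stimuli: 0.190 pp (CI across samples)
#> Bound 0.40 pp: PASS
```

The per-stimulus rows give the signed mean and mean absolute difference
between measured and target inspired CO2 (in volume percentage points)
after removing transition periods (first 10 s and last 5 s of each box,
last 5 s of the ramp); the headline number is the maximum mean absolute
deviation across stimuli, judged against a 0.4 pp bound.

A thin command-line wrapper over the same functions lives at
`inst/cli/co2challenge.R` (`simulate` / `analyze` / `report`), with
ready-made configurations for the three experimental arms under
`inst/extdata/`: ventilated test lung with admixture, spontaneous subject
with admixture, and spontaneous subject with the reservoir reference.

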