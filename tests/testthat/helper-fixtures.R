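# Fixtures are generated in code: synthetic capnograms with known breath
# structure, and short protocols for fast closed-loop runs.

# Square-wave capnogram: insp_s of inspired-level gas, then exp_s of
# end-tidal-level gas, repeated. Optional exponential expiratory rise.
square_capnogram <- function(duration = 60, fs = 60, insp_s = 2, exp_s = 3,
                             insp_level = 0, et_level = 5, exp_tau = 0,
                             noise_sd = 0, seed = NULL) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  period <- insp_s + exp_s
  tau <- tt %% period
  x <- ifelse(tau < insp_s, insp_level,
              if (exp_tau > 0) {
                insp_level + (et_level - insp_level) *
                  (1 - exp(-(tau - insp_s) / exp_tau))
              } else et_level)
  if (exp_tau > 0) {
    expi <- tau >= insp_s
    x[expi] <- insp_level + (et_level - insp_level) *
      (1 - exp(-(tau[expi] - insp_s) / exp_tau))
    x[!expi] <- insp_level
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(length(x), 0, noise_sd)
  }
  data.frame(t_s = tt, fco2_percent = x)
}

box_protocol <- function(baseline = 30, box = 150, level = 0.05) {
  stimulus_protocol(list(stimulus_segment("baseline", baseline),
                         stimulus_segment("box", box, level)),
                    name = "box")
}

quiet_circuit <- function(...) circuit_config(analyzer_noise_sd = 0, ...)

default_vent <- function(mode = "volume_control", ...) {
  ventilator_scenario(ventilator_settings(mode, tidal_volume = 500,
                                          t_insp = 1.5, rate = 12, ...),
                      lung_mechanics())
}
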