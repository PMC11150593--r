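#' Ventilator settings
#'
#' Settings of the mechanical ventilator driving the test lung. In volume
#' control the ventilator delivers a fixed tidal volume at constant
#' inspiratory flow; in pressure control it applies a fixed inspiratory
#' pressure above PEEP for `t_insp` seconds, so the delivered volume
#' depends only on pressure, inspiratory time and the lung compliance.
#'
#' @param mode `"volume_control"` or `"pressure_control"`.
#' @param tidal_volume Set tidal volume, mL (volume control).
#' @param p_insp Inspiratory pressure above PEEP, cmH2O (pressure control).
#' @param t_insp Inspiratory time, s.
#' @param rate Breathing rate, breaths/min.
#' @param peep Positive end-expiratory pressure, cmH2O.
#' @return An object of class `"ventilator_settings"`.
#' @export
ventilator_settings <- function(mode = c("volume_control", "pressure_control"),
                                tidal_volume = 500, p_insp = 15,
                                t_insp = 1.5, rate = 12, peep = 5) {
  mode <- match.arg(mode)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (t_insp <= 0 || t_insp >= 60 / rate) {
    stop("t_insp must be positive and below the breath period", call. = FALSE)
  }
  if (mode == "volume_control" && tidal_volume <= 0) {
    stop("volume control requires tidal_volume > 0", call. = FALSE)
  }
  if (mode == "pressure_control" && p_insp <= 0) {
    stop("pressure control requires p_insp > 0", call. = FALSE)
  }
  structure(list(mode = mode, tidal_volume = tidal_volume, p_insp = p_insp,
                 t_insp = t_insp, rate = rate, peep = peep),
            class = "ventilator_settings")
}

#' Passive lung mechanics (test lung)
#'
#' @param compliance Compliance, mL/cmH2O.
#' @param resistance Airway resistance, cmH2O/(L/s).
#' @param frc Gas store (functional residual capacity), mL.
#' @param dead_space Series dead space, mL.
#' @return An object of class `"lung_mechanics"`.
#' @export
lung_mechanics <- function(compliance = 50, resistance = 5, frc = 3000,
                           dead_space = 150) {
  if (any(c(compliance, resistance, frc, dead_space) <= 0)) {
    stop("all lung mechanics parameters must be positive", call. = FALSE)
  }
  if (dead_space >= frc) stop("dead_space must be below frc", call. = FALSE)
  structure(list(compliance = compliance, resistance = resistance,
                 frc = frc, dead_space = dead_space),
            class = "lung_mechanics")
}

#' Ventilated test-lung scenario
#'
#' Combines ventilator settings with passive lung mechanics. The test lung
#' neither consumes O2 nor produces CO2, so after washout expired gas
#' equals inspired gas.
#'
#' @param settings A [ventilator_settings()] object.
#' @param mech A [lung_mechanics()] object.
#' @return An object of class `"ventilator_scenario"`.
#' @export
ventilator_scenario <- function(settings = ventilator_settings(),
                                mech = lung_mechanics()) {
  stopifnot(inherits(settings, "ventilator_settings"),
            inherits(mech, "lung_mechanics"))
  structure(list(settings = settings, mech = mech),
            class = "ventilator_scenario")
}

#' Spontaneously breathing subject model
#'
#' A minimal gas-exchange model of a resting adult: fixed tidal volume,
#' baseline rate, metabolic O2 uptake and CO2 output, series dead space,
#' FRC as the alveolar mixing volume, and a linear chemoreflex that scales
#' alveolar ventilation (via the breathing rate) with the rise of alveolar
#' PCO2 above its baseline.
#'
#' @param tidal_volume Tidal volume, mL.
#' @param rate_baseline Baseline breathing rate, breaths/min.
#' @param vo2 O2 consumption, L/min.
#' @param vco2 CO2 production, L/min.
#' @param dead_space Series dead space, mL; must be below `tidal_volume`.
#' @param frc Functional residual capacity, mL.
#' @param chemoreflex_gain Fractional increase in alveolar ventilation per
#'   kPa rise of alveolar PCO2 above baseline (default 0.3 /kPa).
#' @return An object of class `"subject_model"`.
#' @export
subject_model <- function(tidal_volume = 500, rate_baseline = 14,
                          vo2 = 0.25, vco2 = 0.20, dead_space = 150,
                          frc = 3000, chemoreflex_gain = 0.3) {
  if (tidal_volume <= dead_space) {
    stop("tidal_volume must exceed dead_space", call. = FALSE)
  }
  if (vo2 <= 0 || vco2 <= 0) stop("vo2 and vco2 must be positive",
                                  call. = FALSE)
  if (rate_baseline <= 0 || frc <= 0 || dead_space <= 0) {
    stop("rate_baseline, frc and dead_space must be positive", call. = FALSE)
  }
  structure(list(tidal_volume = tidal_volume, rate_baseline = rate_baseline,
                 vo2 = vo2, vco2 = vco2, dead_space = dead_space, frc = frc,
                 chemoreflex_gain = chemoreflex_gain),
            class = "subject_model")
}

#' Breathing-circuit configuration
#'
#' Geometry and analyzer parameters of the inspiratory limb between the
#' additional-gas inlet and the sampling port. With the inlet near the
#' flow sensor (ventilator circuit) the injected mixture must traverse the
#' humidifier mixing volume and the tubing before reaching the sampling
#' port; with the inlet near the sampling port (subject circuit) only a
#' small port volume intervenes, giving a much faster concentration
#' response.
#'
#' @param inlet_position `"near_sampling_port"` or `"near_flow_sensor"`.
#' @param mixing_volume Humidifier mixing volume, mL (default 300).
#' @param transport_volume Tubing volume between humidifier and sampling
#'   port, mL (default 500).
#' @param port_volume Inlet-to-port volume used when the inlet sits near
#'   the sampling port, mL (default 50).
#' @param n_compartments Number of well-mixed compartments the
#'   inlet-to-port volume is split into (default 3).
#' @param sampling_delay Sidestream analyzer transit delay, s (default 3).
#' @param sample_rate Analyzer sampling rate, Hz (default 60).
#' @param analyzer_noise_sd Additive Gaussian noise SD on the percent
#'   readings (default 0.05 percentage points).
#' @return An object of class `"circuit_config"`.
#' @export
circuit_config <- function(inlet_position = c("near_sampling_port",
                                              "near_flow_sensor"),
                           mixing_volume = 300, transport_volume = 500,
                           port_volume = 50, n_compartments = 3,
                           sampling_delay = 3, sample_rate = 60,
                           analyzer_noise_sd = 0.05) {
  inlet_position <- match.arg(inlet_position)
  if (any(c(mixing_volume, transport_volume, port_volume) < 0)) {
    stop("circuit volumes must be non-negative", call. = FALSE)
  }
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (sampling_delay < 0 || analyzer_noise_sd < 0) {
    stop("sampling_delay and analyzer_noise_sd must be non-negative",
         call. = FALSE)
  }
  structure(list(inlet_position = inlet_position,
                 mixing_volume = mixing_volume,
                 transport_volume = transport_volume,
                 port_volume = port_volume,
                 n_compartments = max(1L, as.integer(n_compartments)),
                 sampling_delay = sampling_delay, sample_rate = sample_rate,
                 analyzer_noise_sd = analyzer_noise_sd),
            class = "circuit_config")
}

#' Ventilator inspiratory flow waveform
#'
#' Inspiratory flow at the ventilator outlet as a function of time:
#' constant `tidal_volume / t_insp` in volume control, and the exponential
#' `(p_insp / resistance) * exp(-tau / (resistance * compliance))` in
#' pressure control, zero during expiration, periodic with period
#' `60 / rate`.
#'
#' @param settings A [ventilator_settings()] object.
#' @param mech A [lung_mechanics()] object.
#' @param t Time(s), s.
#' @return Inspiratory flow(s), L/min.
#' @examples
#' ventilator_flow(ventilator_settings(tidal_volume = 500, t_insp = 1.5),
#'                 lung_mechanics(), 0.5) # 20 L/min
#' @export
ventilator_flow <- function(settings, mech, t) {
  stopifnot(inherits(settings, "ventilator_settings"),
            inherits(mech, "lung_mechanics"))
  period <- 60 / settings$rate
  tau <- t %% period
  insp <- tau < settings$t_insp
  if (settings$mode == "volume_control") {
    q <- settings$tidal_volume / 1000 / settings$t_insp * 60
    ifelse(insp, q, 0)
  } else {
    rc <- mech$resistance * mech$compliance / 1000
    ifelse(insp, settings$p_insp / mech$resistance * exp(-tau / rc) * 60, 0)
  }
}

#' Chemoreflex breathing pattern
#'
#' Scales the subject's alveolar ventilation by
#' `max(0, 1 + chemoreflex_gain * (alveolar_pco2 - baseline_pco2))`,
#' applied to the breathing rate (tidal volume is held fixed).
#'
#' @param subject A [subject_model()].
#' @param alveolar_pco2 Current alveolar PCO2, kPa.
#' @param baseline_pco2 Baseline alveolar PCO2, kPa.
#' @return List with `rate` (breaths/min), `tidal_volume` (mL), `va`
#'   (alveolar ventilation, L/min) and `scale`.
#' @export
spontaneous_ventilation <- function(subject, alveolar_pco2, baseline_pco2) {
  stopifnot(inherits(subject, "subject_model"))
  scale <- max(0, 1 + subject$chemoreflex_gain *
                 (alveolar_pco2 - baseline_pco2))
  rate <- subject$rate_baseline * scale
  list(rate = rate, tidal_volume = subject$tidal_volume,
       va = rate * (subject$tidal_volume - subject$dead_space) / 1000,
       scale = scale)
}

# mmHg per kPa; alveolar partial pressure assumes 760 mmHg ambient and
# 47 mmHg water vapor at body temperature
.fraction_to_kpa <- function(fraction, p_atm = 760, p_h2o = 47) {
  fraction * (p_atm - p_h2o) * 0.1333224
}

#' Steady-state alveolar gas fractions
#'
#' The steady-state alveolar balance for a subject with alveolar
#' ventilation `VA = rate * (tidal_volume - dead_space)`:
#' `FO2A = FO2i - VO2 / VA` and `FCO2A = FCO2i + VCO2 / VA`. Results are
#' clipped to `[0, 1]` with a warning if clipping occurs.
#'
#' @param inspired [gas_fractions()] of the inspired gas.
#' @param subject A [subject_model()].
#' @return Alveolar [gas_fractions()].
#' @examples
#' steady_state_alveolar(gas_fractions(0, 0.21),
#'                       subject_model(tidal_volume = 500, rate_baseline = 10,
#'                                     dead_space = 100, vco2 = 0.2))
#' @export
steady_state_alveolar <- function(inspired, subject) {
  stopifnot(inherits(inspired, "gas_fractions"),
            inherits(subject, "subject_model"))
  va <- subject$rate_baseline * (subject$tidal_volume - subject$dead_space) /
    1000
  if (va <= 0) stop("alveolar ventilation must be positive", call. = FALSE)
  fo2 <- inspired$fo2 - subject$vo2 / va
  fco2 <- inspired$fco2 + subject$vco2 / va
  if (fo2 < 0 || fo2 > 1 || fco2 < 0 || fco2 > 1) {
    warning("steady-state alveolar fractions clipped to [0, 1]",
            call. = FALSE)
  }
  gas_fractions(min(1, max(0, fco2)), min(1, max(0, fo2)))
}

#' Integrate the dynamic alveolar compartment
#'
#' Fixed-step integration of the alveolar balance
#' `dFA/dt = (VA * (Fi - FA) +/- Vgas) / FRC` under constant inspired gas
#' and constant alveolar ventilation, using the exact exponential update
#' per step. With time the state converges to the
#' [steady_state_alveolar()] solution.
#'
#' @param inspired [gas_fractions()] of the (constant) inspired gas.
#' @param subject A [subject_model()].
#' @param duration Integration time, s.
#' @param dt Step, s (default 0.01).
#' @param init Initial alveolar [gas_fractions()] (default: ambient air).
#' @return [gas_fractions()] at `duration`.
#' @export
alveolar_compartment <- function(inspired, subject, duration, dt = 0.01,
                                 init = gas_fractions(0.0, 0.209)) {
  stopifnot(inherits(inspired, "gas_fractions"),
            inherits(subject, "subject_model"),
            inherits(init, "gas_fractions"))
  va <- subject$rate_baseline * (subject$tidal_volume - subject$dead_space) /
    1000 / 60                      # L/s
  frc <- subject$frc / 1000        # L
  fss_co2 <- inspired$fco2 + (subject$vco2 / 60) / va
  fss_o2 <- inspired$fo2 - (subject$vo2 / 60) / va
  a <- 1 - exp(-va * dt / frc)
  fco2 <- init$fco2
  fo2 <- init$fo2
  n <- max(1L, round(duration / dt))
  for (i in seq_len(n)) {
    fco2 <- fco2 + (fss_co2 - fco2) * a
    fo2 <- fo2 + (fss_o2 - fo2) * a
  }
  gas_fractions(min(1, max(0, fco2)), min(1, max(0, fo2)))
}

#' Closed-loop simulation of an inspired-CO2 challenge
#'
#' Runs the full loop at a fixed step `dt`: flow source (ventilator or
#' spontaneous subject), flow sensor (gain-scaled), proportional
#' controller setpoint, inlet injection, transport through well-mixed
#' circuit compartments in series, inspired gas at the airway, dynamic
#' alveolar compartment, expired gas stream, and a sidestream analyzer
#' sampling at the port with a transit delay and additive Gaussian noise.
#' Circuit compartment and dead-space updates use the exact exponential
#' solution for a well-mixed volume under piecewise-constant inflow, so
#' the integration is unconditionally stable.
#'
#' The reservoir reference system is simulated by drawing the premixed
#' target gas from a finite reservoir refilled at the configured fresh-gas
#' flow; when the reservoir runs empty mid-inspiration the subject draws
#' ambient air, reproducing the late-inspiratory concentration decline
#' characteristic of non-excessive fresh-gas flows.
#'
#' @param protocol A [stimulus_protocol()].
#' @param scenario A [ventilator_scenario()] or [subject_model()].
#' @param circuit A [circuit_config()].
#' @param control A [controller_config()].
#' @param limits [safety_limits()] applied to the protocol target.
#' @param seed Integer seed for the analyzer noise (recorded in the
#'   result).
#' @param dt Integration step, s (default 0.01).
#' @return An object of class `"co2_sim"` with elements `trace` (data
#'   frame `t_s`, `fco2_percent`, `fo2_percent`, `flow_lpm` at the
#'   analyzer), `breaths` (per-breath truth: delivered inspired fractions,
#'   delivered volume, mean added flow, target), `state` (10 Hz ground
#'   truth state history), `seed`, `dt` and a config echo.
#' @export
simulate_closed_loop <- function(protocol, scenario,
                                 circuit = circuit_config(),
                                 control = controller_config(),
                                 limits = safety_limits(),
                                 seed = 1, dt = 0.01) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(circuit, "circuit_config"),
            inherits(control, "controller_config"))
  is_vent <- inherits(scenario, "ventilator_scenario")
  if (!is_vent && !inherits(scenario, "subject_model")) {
    stop("scenario must be a ventilator_scenario or a subject_model",
         call. = FALSE)
  }
  if (is_vent && control$system == "reservoir") {
    stop("the reservoir system cannot drive a ventilator circuit",
         call. = FALSE)
  }

  dur <- protocol_duration(protocol)
  nstep <- round(dur / dt)
  tgrid <- (seq_len(nstep) - 1) * dt
  amb <- control$ambient
  f_add <- control$additional_fco2
  g <- control$sensor_gain
  cap_ls <- control$setpoint_cap_lpm / 60

  target <- clamp_target(target_fco2i(protocol, tgrid), amb, limits,
                         additional_fco2 = f_add, quiet = TRUE)
  ratio <- additional_flow_ratio(target, amb, f_add)
  res_fco2 <- target                      # reservoir mixture tracks target
  res_fo2 <- rep(min(control$reservoir$fo2, 1 - target), length.out = nstep)

  # circuit chain between inlet and sampling port
  if (circuit$inlet_position == "near_flow_sensor") {
    k <- circuit$n_compartments
    vch <- if (k >= 2) {
      c(circuit$mixing_volume, rep(circuit$transport_volume / (k - 1), k - 1))
    } else {
      circuit$mixing_volume + circuit$transport_volume
    }
  } else {
    vch <- circuit$port_volume
  }
  vch <- pmax(vch, 1) / 1000              # L; floor avoids zero volumes
  k <- length(vch)

  if (is_vent) {
    settings <- scenario$settings
    mech <- scenario$mech
    rate0 <- settings$rate
    t_insp0 <- settings$t_insp
    vd <- mech$dead_space / 1000
    frc <- mech$frc / 1000
    vo2_ls <- 0
    vco2_ls <- 0
    rc <- mech$resistance * mech$compliance / 1000
    tau_e <- max(rc, 0.2)
    fa_co2 <- amb$fco2
    fa_o2 <- amb$fo2
    pco2_base <- NA_real_
  } else {
    vd <- scenario$dead_space / 1000
    frc <- scenario$frc / 1000
    vo2_ls <- scenario$vo2 / 60
    vco2_ls <- scenario$vco2 / 60
    fa0 <- steady_state_alveolar(gas_fractions(amb$fco2, amb$fo2), scenario)
    fa_co2 <- fa0$fco2
    fa_o2 <- fa0$fo2
    pco2_base <- .fraction_to_kpa(fa_co2)
  }

  chain_co2 <- rep(amb$fco2, k)
  chain_o2 <- rep(amb$fo2, k)
  ds_co2 <- fa_co2
  ds_o2 <- fa_o2

  res_vcap <- control$reservoir$volume_ml / 1000
  res_vol <- res_vcap
  res_fill_ls <- control$reservoir$total_flow_lpm / 60
  reservoir <- control$system == "reservoir"

  sig_co2 <- numeric(nstep)
  sig_o2 <- numeric(nstep)
  sig_flow <- numeric(nstep)

  every <- max(1L, round(0.1 / dt))
  nrec <- ceiling(nstep / every)
  st_t <- numeric(nrec); st_target <- numeric(nrec)
  st_aw_co2 <- numeric(nrec); st_fa_co2 <- numeric(nrec)
  st_fa_o2 <- numeric(nrec); st_qadd <- numeric(nrec)
  irec <- 0L

  breaths <- vector("list", ceiling(dur / 1.0))
  nb <- 0L

  # per-breath state
  breath_start <- 0
  new_breath <- function(t) {
    if (is_vent) {
      period <- 60 / rate0
      list(period = period, t_insp = t_insp0, rate = rate0, amp = NA_real_)
    } else {
      pat <- spontaneous_ventilation(scenario, .fraction_to_kpa(fa_co2),
                                     pco2_base)
      rate <- max(pat$rate, 1e-6)
      period <- 60 / rate
      t_insp <- 0.4 * period
      amp <- (scenario$tidal_volume / 1000) * pi / (2 * t_insp)  # L/s peak
      list(period = period, t_insp = t_insp, rate = rate, amp = amp)
    }
  }
  bp <- new_breath(0)
  del_c <- 0; del_o <- 0; den <- 0; qadd_int <- 0; cumv <- 0
  exp_amp <- 0

  finalize_breath <- function(t_end) {
    nb <<- nb + 1L
    breaths[[nb]] <<- c(t_start = breath_start, t_insp_end = breath_start +
                          bp$t_insp, t_end = t_end,
                        delivered_fco2i_percent =
                          if (den > 0) 100 * del_c / den else NA_real_,
                        delivered_fo2i_percent =
                          if (den > 0) 100 * del_o / den else NA_real_,
                        tidal_volume_ml = 1000 * den,
                        q_add_mean_lpm =
                          if (bp$t_insp > 0) 60 * qadd_int / bp$t_insp else 0,
                        target_fco2i_percent =
                          100 * target[min(nstep, max(1L, round(
                            (breath_start + bp$t_insp / 2) / dt) + 1L))],
                        rate_bpm = bp$rate)
  }

  for (i in seq_len(nstep)) {
    t <- tgrid[i]
    if (t >= breath_start + bp$period - 1e-9) {
      finalize_breath(breath_start + bp$period)
      breath_start <- breath_start + bp$period
      bp <- new_breath(t)
      del_c <- 0; del_o <- 0; den <- 0; qadd_int <- 0; cumv <- 0
    }
    tau <- t - breath_start
    if (tau < bp$t_insp) {
      # ---- inspiration ----
      if (is_vent) {
        if (settings$mode == "volume_control") {
          q_resp <- settings$tidal_volume / 1000 / settings$t_insp
          q_add <- min(cap_ls, ratio[i] * g * q_resp)
          q_lung <- q_resp + q_add
        } else {
          q_tot <- settings$p_insp / mech$resistance * exp(-tau / rc)
          q_add <- q_tot * ratio[i] * g / (1 + ratio[i] * g)
          if (q_add > cap_ls) q_add <- cap_ls
          q_resp <- q_tot - q_add
          q_lung <- q_tot
        }
      } else {
        q_tot <- bp$amp * sin(pi * tau / bp$t_insp)
        if (reservoir) {
          q_resp <- q_tot
          q_add <- 0
          q_lung <- q_tot
        } else {
          q_add <- q_tot * ratio[i] * g / (1 + ratio[i] * g)
          if (q_add > cap_ls) q_add <- cap_ls
          q_resp <- q_tot - q_add
          q_lung <- q_tot
        }
      }
      if (reservoir) {
        if (res_vol > 0) {
          mix_co2 <- res_fco2[i]
          mix_o2 <- res_fo2[i]
        } else {
          mix_co2 <- amb$fco2
          mix_o2 <- amb$fo2
        }
        res_vol <- min(res_vcap, max(0, res_vol +
                                       (res_fill_ls - q_lung) * dt))
      } else if (q_lung > 0) {
        mix_co2 <- (amb$fco2 * q_resp + f_add * q_add) / q_lung
        mix_o2 <- amb$fo2 * q_resp / q_lung
      } else {
        mix_co2 <- chain_co2[1]
        mix_o2 <- chain_o2[1]
      }
      if (q_lung > 0) {
        a <- 1 - exp(-q_lung * dt / vch)
        inp_co2 <- c(mix_co2, chain_co2[-k])
        inp_o2 <- c(mix_o2, chain_o2[-k])
        chain_co2 <- chain_co2 + (inp_co2 - chain_co2) * a
        chain_o2 <- chain_o2 + (inp_o2 - chain_o2) * a
      }
      aw_co2 <- chain_co2[k]
      aw_o2 <- chain_o2[k]
      if (q_lung > 0) {
        b <- 1 - exp(-q_lung * dt / vd)
        ds_co2 <- ds_co2 + (aw_co2 - ds_co2) * b
        ds_o2 <- ds_o2 + (aw_o2 - ds_o2) * b
        cumv <- cumv + q_lung * dt
        if (cumv > vd) {
          fa_co2 <- fa_co2 + (aw_co2 - fa_co2) * (q_lung * dt / frc)
          fa_o2 <- fa_o2 + (aw_o2 - fa_o2) * (q_lung * dt / frc)
        }
        del_c <- del_c + aw_co2 * q_lung * dt
        del_o <- del_o + aw_o2 * q_lung * dt
        den <- den + q_lung * dt
        qadd_int <- qadd_int + q_add * dt
      }
      sig_co2[i] <- aw_co2
      sig_o2[i] <- aw_o2
      sig_flow[i] <- if (reservoir) q_lung * 60 else g * q_resp * 60
    } else {
      # ---- expiration ----
      tau_x <- tau - bp$t_insp
      t_exp <- bp$period - bp$t_insp
      if (tau_x < dt) exp_amp <- den   # volume to expel this expiration (L)
      if (is_vent) {
        q_exp <- if (t_exp > 0) {
          exp_amp / (tau_e * (1 - exp(-t_exp / tau_e))) * exp(-tau_x / tau_e)
        } else 0
      } else {
        q_exp <- if (t_exp > 0) exp_amp * pi / (2 * t_exp) *
          sin(pi * tau_x / t_exp) else 0
      }
      if (q_exp > 0) {
        b <- 1 - exp(-q_exp * dt / vd)
        ds_co2 <- ds_co2 + (fa_co2 - ds_co2) * b
        ds_o2 <- ds_o2 + (fa_o2 - ds_o2) * b
      }
      if (reservoir) {
        res_vol <- min(res_vcap, res_vol + res_fill_ls * dt)
      }
      q_add <- 0
      sig_co2[i] <- ds_co2
      sig_o2[i] <- ds_o2
      sig_flow[i] <- 0
    }
    fa_co2 <- fa_co2 + vco2_ls * dt / frc
    fa_o2 <- fa_o2 - vo2_ls * dt / frc
    if (fa_co2 > 1) fa_co2 <- 1
    if (fa_co2 < 0) fa_co2 <- 0
    if (fa_o2 > 1) fa_o2 <- 1
    if (fa_o2 < 0) fa_o2 <- 0
    if (!is.finite(fa_co2) || !is.finite(chain_co2[k])) {
      stop(sprintf("non-finite simulator state at t = %.2f s", t),
           call. = FALSE)
    }
    if ((i - 1L) %% every == 0L) {
      irec <- irec + 1L
      st_t[irec] <- t
      st_target[irec] <- 100 * target[i]
      st_aw_co2[irec] <- 100 * chain_co2[k]
      st_fa_co2[irec] <- 100 * fa_co2
      st_fa_o2[irec] <- 100 * fa_o2
      st_qadd[irec] <- 60 * q_add
    }
  }
  if (den > 0 || tgrid[nstep] - breath_start > bp$t_insp) {
    finalize_breath(dur)
  }

  breaths_df <- as.data.frame(do.call(rbind, breaths[seq_len(nb)]))

  # ---- analyzer sampling: transit delay + seeded Gaussian noise ----
  fs <- circuit$sample_rate
  ns <- floor(dur * fs)
  ts <- (seq_len(ns) - 1) / fs
  idx <- floor((ts - circuit$sampling_delay) / dt) + 1L
  pre <- idx < 1L
  idx[pre] <- 1L
  co2 <- 100 * sig_co2[idx]
  o2 <- 100 * sig_o2[idx]
  fl <- sig_flow[idx]
  co2[pre] <- 100 * amb$fco2
  o2[pre] <- 100 * amb$fo2
  fl[pre] <- 0
  if (circuit$analyzer_noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
    co2 <- co2 + stats::rnorm(ns, 0, circuit$analyzer_noise_sd)
    o2 <- o2 + stats::rnorm(ns, 0, circuit$analyzer_noise_sd)
  }
  trace <- data.frame(t_s = ts, fco2_percent = co2, fo2_percent = o2,
                      flow_lpm = fl)
  state <- data.frame(t_s = st_t[seq_len(irec)],
                      target_fco2i_percent = st_target[seq_len(irec)],
                      airway_fco2_percent = st_aw_co2[seq_len(irec)],
                      alveolar_fco2_percent = st_fa_co2[seq_len(irec)],
                      alveolar_fo2_percent = st_fa_o2[seq_len(irec)],
                      q_add_lpm = st_qadd[seq_len(irec)])
  structure(list(trace = trace, breaths = breaths_df, state = state,
                 seed = seed, dt = dt,
                 config = list(protocol = protocol, scenario = scenario,
                               circuit = circuit, control = control,
                               limits = limits)),
            class = "co2_sim")
}

#' @export
print.co2_sim <- function(x, ...) {
  cat(sprintf(paste0("<co2_sim> %.0f s, %d analyzer samples at %g Hz, ",
                     "%d breaths, seed %d\n"),
              max(x$trace$t_s), nrow(x$trace),
              x$config$circuit$sample_rate, nrow(x$breaths), x$seed))
  invisible(x)
}
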