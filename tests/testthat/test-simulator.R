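test_that("constructors validate their physiological invariants", {
  expect_error(ventilator_settings(rate = 12, t_insp = 6), "breath period")
  expect_error(ventilator_settings("volume_control", tidal_volume = 0),
               "tidal_volume")
  expect_error(lung_mechanics(dead_space = 4000), "below frc")
  expect_error(subject_model(tidal_volume = 100, dead_space = 150),
               "exceed dead_space")
  expect_error(circuit_config(sample_rate = 0), "positive")
})

test_that("ventilator flow waveforms match their closed forms", {
  mech <- lung_mechanics(compliance = 50, resistance = 5)
  vc <- ventilator_settings("volume_control", tidal_volume = 500,
                            t_insp = 1.5, rate = 12)
  expect_equal(ventilator_flow(vc, mech, 0.5), 20)  # 0.5 L / 1.5 s * 60
  expect_equal(ventilator_flow(vc, mech, 2.5), 0)   # expiration
  expect_equal(ventilator_flow(vc, mech, 5 + 0.5), 20)  # periodic
  pc <- ventilator_settings("pressure_control", p_insp = 15, t_insp = 1.5,
                            rate = 12)
  rc <- 5 * 50 / 1000
  expect_equal(ventilator_flow(pc, mech, 0.1),
               15 / 5 * exp(-0.1 / rc) * 60)
  # exponential limit: flow decays monotonically toward zero
  flows <- ventilator_flow(pc, mech, c(0.25, 0.75, 1.25, 1.49))
  expect_true(all(diff(flows) < 0))
  expect_lt(flows[4], 15 / 5 * 60 * exp(-1.49 / rc) + 1e-9)
  expect_equal(ventilator_flow(pc, mech, 3), 0)
})

test_that("chemoreflex scales alveolar ventilation linearly with a floor", {
  s0 <- subject_model(chemoreflex_gain = 0)
  base <- spontaneous_ventilation(s0, 7, 5)
  expect_equal(base$rate, s0$rate_baseline)
  s <- subject_model(chemoreflex_gain = 0.3)
  ref <- spontaneous_ventilation(s, 5, 5)
  up <- spontaneous_ventilation(s, 6, 5)
  expect_equal(up$va / ref$va, 1.3)
  floor <- spontaneous_ventilation(s, 0, 5)
  expect_equal(floor$va, 0)
})

test_that("steady-state alveolar balance matches direct substitution", {
  # VA = 10 * (500 - 100) / 1000 = 4 L/min
  s4 <- subject_model(tidal_volume = 500, rate_baseline = 10,
                      dead_space = 100, vco2 = 0.2, vo2 = 0.25)
  expect_equal(steady_state_alveolar(gas_fractions(0, 0.21), s4)$fco2, 0.05)
  # VA = 10 * (600 - 100) / 1000 = 5 L/min
  s5 <- subject_model(tidal_volume = 600, rate_baseline = 10,
                      dead_space = 100, vco2 = 0.2, vo2 = 0.25)
  expect_equal(steady_state_alveolar(gas_fractions(0, 0.21), s5)$fo2, 0.16)
  # degenerate: no CO2 production leaves inspired CO2 unchanged
  s0 <- subject_model(vco2 = 1e-12)
  expect_equal(steady_state_alveolar(gas_fractions(0.03, 0.21), s0)$fco2,
               0.03, tolerance = 1e-9)
  expect_warning(steady_state_alveolar(gas_fractions(0, 0.21),
                                       subject_model(vo2 = 2)), "clipped")
})

test_that("dynamic alveolar compartment converges to the steady state", {
  subj <- subject_model()
  insp <- gas_fractions(0.05, 0.19)
  ss <- steady_state_alveolar(insp, subj)
  fin <- alveolar_compartment(insp, subj, duration = 600)
  expect_equal(fin$fco2, ss$fco2, tolerance = 1e-6)
  expect_equal(fin$fo2, ss$fo2, tolerance = 1e-6)
})

test_that("noiseless subject loop delivers the target at box plateaus", {
  p <- box_protocol(30, 90, 0.05)
  sim <- simulate_closed_loop(p, subject_model(), quiet_circuit(),
                              controller_config(), seed = 1)
  b <- sim$breaths
  plateau <- b$t_start >= 60 & b$t_insp_end <= 118
  expect_gt(sum(plateau), 5)
  expect_true(all(abs(b$delivered_fco2i_percent[plateau] - 5) < 0.05))
})

test_that("all-baseline protocol leaves inspired CO2 at ambient", {
  p <- stimulus_protocol(list(stimulus_segment("baseline", 60)), "flat")
  sim <- simulate_closed_loop(p, subject_model(), quiet_circuit(),
                              controller_config(), seed = 1)
  expect_lt(max(sim$state$airway_fco2_percent), 1e-9)
  expect_lt(max(sim$breaths$delivered_fco2i_percent), 1e-9)
  expect_lt(max(sim$trace$fco2_percent[sim$trace$flow_lpm > 0]), 1e-9)
})

test_that("flow-sensor gain bias produces the closed-form plateau offset", {
  p <- box_protocol(30, 150, 0.05)
  g <- 0.93
  sim <- simulate_closed_loop(p, default_vent(), quiet_circuit("near_flow_sensor"),
                              controller_config(sensor_gain = g), seed = 1)
  b <- sim$breaths
  plateau <- b$t_start >= 120 & b$t_insp_end <= 178
  got <- mean(b$delivered_fco2i_percent[plateau])
  rg <- (1 / 19) * g
  expect_equal(got, 100 * rg / (1 + rg), tolerance = 1e-4)
})

test_that("simulations are deterministic per seed", {
  p <- box_protocol(20, 40, 0.03)
  circ <- circuit_config(analyzer_noise_sd = 0.05)
  s1 <- simulate_closed_loop(p, subject_model(), circ, controller_config(),
                             seed = 7)
  s2 <- simulate_closed_loop(p, subject_model(), circ, controller_config(),
                             seed = 7)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$breaths, s2$breaths)
  s3 <- simulate_closed_loop(p, subject_model(), circ, controller_config(),
                             seed = 8)
  expect_false(identical(s1$trace$fco2_percent, s3$trace$fco2_percent))
})

test_that("halving the integration step barely moves delivered fractions", {
  p <- box_protocol(30, 90, 0.05)
  s1 <- simulate_closed_loop(p, default_vent(), quiet_circuit("near_flow_sensor"),
                             controller_config(), seed = 1, dt = 0.01)
  s2 <- simulate_closed_loop(p, default_vent(), quiet_circuit("near_flow_sensor"),
                             controller_config(), seed = 1, dt = 0.005)
  n <- min(nrow(s1$breaths), nrow(s2$breaths))
  diff_frac <- abs(s1$breaths$delivered_fco2i_percent[1:n] -
                     s2$breaths$delivered_fco2i_percent[1:n]) / 100
  expect_lt(max(diff_frac), 1e-4)
})

test_that("inlet near the flow sensor slows the concentration rise", {
  p <- box_protocol(30, 150, 0.05)
  rise_time <- function(circ) {
    s <- simulate_closed_loop(p, default_vent(), circ, controller_config(),
                              seed = 1)
    st <- s$state
    sel <- st$t_s >= 30
    x <- st$airway_fco2_percent[sel]
    tt <- st$t_s[sel]
    plateau <- mean(x[tt > 150])
    tt[which(x >= 0.9 * plateau)[1]] - tt[which(x >= 0.1 * plateau)[1]]
  }
  slow <- rise_time(quiet_circuit("near_flow_sensor"))
  fast <- rise_time(quiet_circuit("near_sampling_port"))
  expect_gt(slow, fast)
  expect_gt(slow, 5)   # multiple breaths of tubing washout
  expect_lt(fast, 2)
})

test_that("admixture grows volume-control tidal volume but not pressure-control", {
  base <- stimulus_protocol(list(stimulus_segment("baseline", 120)), "b")
  box <- box_protocol(30, 90, 0.05)
  circ <- quiet_circuit("near_flow_sensor")
  tidal <- function(scen, prot) {
    s <- simulate_closed_loop(prot, scen, circ, controller_config(), seed = 1)
    b <- s$breaths
    mean(b$tidal_volume_ml[b$t_start > 60 & b$t_insp_end < 115])
  }
  vc <- default_vent("volume_control")
  pc <- default_vent("pressure_control", p_insp = 12)
  expect_equal(tidal(vc, base), 500, tolerance = 1e-3)
  expect_equal(tidal(vc, box), 500 * (1 + 1 / 19), tolerance = 1e-3)
  expect_equal(tidal(pc, box) / tidal(pc, base), 1, tolerance = 1e-6)
})

test_that("gas fractions stay physical everywhere in the loop", {
  p <- default_protocol()
  sim <- simulate_closed_loop(p, subject_model(), quiet_circuit(),
                              controller_config(), seed = 1)
  with(sim$state, {
    expect_true(all(airway_fco2_percent >= 0 & airway_fco2_percent <= 100))
    expect_true(all(alveolar_fco2_percent >= 0 &
                      alveolar_fco2_percent <= 100))
    expect_true(all(alveolar_fco2_percent + alveolar_fo2_percent <= 100))
  })
  with(sim$trace, {
    expect_true(all(fco2_percent >= 0 & fco2_percent <= 100))
    expect_true(all(fco2_percent + fo2_percent <= 100))
  })
})

test_that("closed-loop alveolar state settles on the two-equation balance", {
  # fixed ventilation (no chemoreflex) and a constant 5 % inspired target
  subj <- subject_model(chemoreflex_gain = 0)
  p <- box_protocol(10, 290, 0.05)
  sim <- simulate_closed_loop(p, subj, quiet_circuit(), controller_config(),
                              seed = 1)
  st <- sim$state
  tail_mean <- mean(st$alveolar_fco2_percent[st$t_s > 270])
  ss <- steady_state_alveolar(gas_fractions(0.05, 0.209 / (1 + 1 / 19)),
                              subj)
  expect_equal(tail_mean, 100 * ss$fco2, tolerance = 0.01)
})

test_that("reservoir arm shows the late-inspiration concentration decline", {
  p <- box_protocol(20, 100, 0.05)
  # high minute ventilation outstrips the 8 L/min fresh-gas flow
  subj <- subject_model(rate_baseline = 20, chemoreflex_gain = 0)
  sim <- simulate_closed_loop(p, subj, quiet_circuit(),
                              controller_config("reservoir"), seed = 1)
  tr <- sim$trace
  # within late box inspirations the port sees ambient (near-zero CO2)
  insp <- tr$flow_lpm > 0 & tr$t_s > 80 & tr$t_s < 115
  expect_gt(max(tr$fco2_percent[insp]), 4.5)  # early inspiration on target
  expect_lt(min(tr$fco2_percent[insp]), 0.5)  # late inspiration diluted
})
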