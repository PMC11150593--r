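test_that("square-wave capnograms segment into the known breath count", {
  tr <- square_capnogram(60, insp_s = 2, exp_s = 3)  # 12 breaths/min
  ph <- detect_breath_phases(tr, "ventilated")
  expect_equal(nrow(ph), 12)
  expect_true(all(ph$insp_start < ph$insp_end))
  expect_true(all(ph$insp_end <= ph$exp_start))
  expect_true(all(ph$exp_start < ph$exp_end))
  expect_true(all(diff(ph$exp_start) > 0))
})

test_that("flat traces and sub-scale artifacts are rejected", {
  tt <- seq(0, 60, by = 1 / 60)
  flat <- data.frame(t_s = tt, fco2_percent = rep(2, length(tt)))
  expect_error(detect_breath_phases(flat, "ventilated"), "no breaths")
  # one short spike inside an inspiration must not add a breath
  tr <- square_capnogram(60, insp_s = 2, exp_s = 3)
  tr$fco2_percent[tr$t_s > 6 & tr$t_s < 6.2] <- 4.5
  expect_equal(nrow(detect_breath_phases(tr, "ventilated")), 12)
})

test_that("spontaneous mode accepts exponential expirations across noise seeds", {
  for (sd in c(0, 0.05, 0.1)) {
    for (seed in 1:3) {
      tr <- square_capnogram(60, insp_s = 2, exp_s = 3, insp_level = 0.2,
                             et_level = 5.5, exp_tau = 0.4, noise_sd = sd,
                             seed = seed)
      ph <- detect_breath_phases(tr, "spontaneous")
      expect_equal(nrow(ph), 12)
    }
  }
})

test_that("inspired and end-tidal values are extracted from their phases", {
  fs <- 60
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tau <- tt %% 5
  # inspiration at a constant 5 %, expiration plateau at 5.6 %
  x <- ifelse(tau < 2, 5, 5.6)
  o2 <- ifelse(tau < 2, 20, 16)
  ph <- detect_breath_phases(square_capnogram(60, insp_s = 2, exp_s = 3),
                             "ventilated")
  rec <- extract_breath_records(data.frame(t_s = tt, fco2_percent = x,
                                           fo2_percent = o2), ph)
  mid <- 3:(nrow(rec) - 1)
  expect_equal(rec$insp_co2_peak[mid], rep(5, length(mid)))
  expect_equal(rec$insp_co2_base[mid], rep(5, length(mid)))
  expect_equal(rec$et_co2[mid], rep(5.6, length(mid)))
  expect_equal(rec$et_o2[mid], rep(16, length(mid)))
  expect_true(all(rec$insp_co2_base <= rec$insp_co2_peak))
})

test_that("reservoir-mode tracking ignores the late-inspiration decline", {
  fs <- 60
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tau <- tt %% 5
  # inspiration (2 s): on-target 5 % for the first two thirds, then
  # dilution to 0; expiration plateau at 7 %
  x <- ifelse(tau < 2, ifelse(tau < 4 / 3, 5, 0), 7)
  tr <- data.frame(t_s = tt, fco2_percent = x)
  ph <- detect_breath_phases(tr, "ventilated", use_flow = FALSE)
  rec_res <- extract_breath_records(tr, ph, "reservoir")
  rec_add <- extract_breath_records(tr, ph, "additional")
  mid <- 3:(nrow(rec_res) - 1)
  expect_true(all(abs(rec_res$insp_co2[mid] - 5) < 0.35))
  # whole-inspiration tracking would be dragged down by the decline
  expect_true(all(rec_add$insp_co2[mid] < 4))
  expect_error(extract_breath_records(tr, ph[0, ]), NA)
  expect_equal(nrow(extract_breath_records(tr, ph[0, ])), 0)
})

test_that("alignment interpolates linearly and shifts ventilated records", {
  rec <- data.frame(t_s = c(0, 2, 4), insp_co2 = c(0, 2, 4))
  out <- align_and_resample(rec, "spontaneous", grid_dt = 1)
  expect_equal(out$t_s, 0:4)
  expect_equal(out$value, 0:4)
  rec2 <- data.frame(t_s = c(10, 12, 14), insp_co2 = c(1, 2, 3))
  shifted <- align_and_resample(rec2, "ventilated", grid_dt = 1)
  expect_equal(shifted$t_s, 2:6)  # all times reduced by exactly 8 s
  expect_equal(shifted$value, seq(1, 3, by = 0.5))
  expect_error(align_and_resample(rec2[1, ], "ventilated"), "at least 2")
})

test_that("binned aggregation averages runs and bootstraps honestly", {
  tt <- seq(0, 59, by = 1)
  one <- data.frame(t_s = tt, value = rep(3, 60))
  agg1 <- bin_and_aggregate(list(one, one, one), n_boot = 200)
  expect_true(all(agg1$mean == 3))
  expect_true(all(agg1$ci_high - agg1$ci_low == 0))  # identical runs
  two <- bin_and_aggregate(list(data.frame(t_s = tt, value = rep(2, 60)),
                                data.frame(t_s = tt, value = rep(4, 60))),
                           n_boot = 200)
  expect_true(all(two$mean == 3))
  expect_true(all(two$ci_low <= two$mean & two$mean <= two$ci_high))
  # order invariance
  r1 <- data.frame(t_s = tt, value = sin(tt / 5))
  r2 <- data.frame(t_s = tt, value = cos(tt / 7))
  r3 <- data.frame(t_s = tt, value = sqrt(tt + 1))
  a <- bin_and_aggregate(list(r1, r2, r3), n_boot = 100, seed = 3)
  b <- bin_and_aggregate(list(r3, r1, r2), n_boot = 100, seed = 3)
  expect_equal(a$mean, b$mean)
  # empty bins flagged missing, not zero
  gap <- data.frame(t_s = c(1, 2, 21, 22), value = c(1, 1, 2, 2))
  g <- bin_and_aggregate(gap, n_boot = 50)
  expect_true(is.na(g$mean[g$n == 0][1]))
  expect_equal(g$n[2], 0)
})

test_that("baseline subtraction references each run's initial window", {
  tt <- seq(0, 119, by = 1)
  run <- data.frame(t_s = tt, value = c(rep(5, 60), rep(5.8, 60)))
  agg <- bin_and_aggregate(run, baseline_subtract = TRUE, n_boot = 50)
  expect_equal(agg$mean[agg$bin_t_s >= 60], rep(0.8, 12), tolerance = 1e-12)
  expect_equal(agg$mean[agg$bin_t_s < 60], rep(0, 12), tolerance = 1e-12)
})

test_that("partial-pressure conversion is linear and invertible", {
  expect_equal(to_partial_pressure(5), 35.65)
  expect_equal(to_partial_pressure(0), 0)
  expect_equal(to_partial_pressure(100), 713)
  x <- c(0.5, 3, 40)
  p <- to_partial_pressure(x)
  expect_equal(p / (713 / 100), x)  # invertible by the same slope
  expect_equal(to_partial_pressure(2 + 3),
               to_partial_pressure(2) + to_partial_pressure(3))
  expect_error(to_partial_pressure(120), "\\[0, 100\\]")
})

test_that("analysis recovers the simulator's delivered inspired fractions", {
  p <- box_protocol(30, 90, 0.03)
  sim <- simulate_closed_loop(p, subject_model(),
                              circuit_config(analyzer_noise_sd = 0.05),
                              controller_config(), seed = 2)
  ph <- detect_breath_phases(sim$trace, "spontaneous")
  rec <- extract_breath_records(sim$trace, ph, "additional")
  b <- sim$breaths
  # match detected breaths (analyzer time base, 3 s delay) to truth breaths
  for (i in seq_len(nrow(rec))) {
    j <- which.min(abs((b$t_start + b$t_insp_end) / 2 + 3 - rec$t_s[i]))
    # skip transition breaths where within-breath change dominates
    if (b$t_start[j] < 35 || (b$t_start[j] > 115 && b$t_start[j] < 125)) next
    expect_lt(abs(rec$insp_co2[i] - b$delivered_fco2i_percent[j]),
              3 * 0.05 + 0.05)
  }
})
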