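test_that("von Mises sampler hits its limits and its moments", {
  set.seed(41)
  # kappa -> Inf collapses to the mean; kappa = 0 is uniform
  expect_equal(rvonmises_phase(5, 0.5, Inf), rep(0.5, 5))
  u <- rvonmises_phase(3000, 0.5, 0)
  expect_lt(circular_summary(u)$resultant_length, 0.05)
  # concentration matches the Bessel ratio at kappa = 8
  x <- rvonmises_phase(3000, 0.7, 8)
  A8 <- besselI(8, 1) / besselI(8, 0)
  expect_lt(abs(circular_summary(x)$resultant_length - A8), 0.02)
  expect_error(rvonmises_phase(5, 0.5, -1), "kappa")
})

test_that("same seed gives identical passes, different passes differ", {
  sc <- scenario_presets("control_overground", seed = 42)
  a <- simulate_pass(sc, 1, 1)
  b <- simulate_pass(sc, 1, 1)
  expect_identical(a$series$RH$contacts, b$series$RH$contacts)
  expect_identical(a$series$LF$contacts, b$series$LF$contacts)
  expect_identical(a$markers$body$x, b$markers$body$x)
  c2 <- simulate_pass(sc, 1, 2)
  expect_false(identical(a$series$RH$contacts, c2$series$RH$contacts))
})

test_that("noiseless alternation yields folded phases of exactly 0.5", {
  sc <- gait_scenario(
    concentration = c(LR_fore = Inf, LR_hind = Inf, HLFL_ipsi = Inf),
    stride_time_cv = 0, disruption_rate = 0, seed = 2
  )
  ps <- simulate_pass(sc)
  samp <- pair_phase_samples(ps$series$RH, ps$series$LH, "LR_hind")
  expect_equal(samp$folded_phase, rep(0.5, nrow(samp)), tolerance = 1e-9)
  samp_f <- pair_phase_samples(ps$series$RF, ps$series$LF, "LR_fore")
  expect_equal(samp_f$folded_phase, rep(0.5, nrow(samp_f)),
               tolerance = 1e-9)
})

test_that("undisrupted tight stepping stays near the band false-positive
           rate", {
  sc <- gait_scenario(disruption_rate = 0,
                      concentration = c(LR_fore = 30, LR_hind = 30,
                                        HLFL_ipsi = 30),
                      n_animals = 4, passes_per_animal = 6, seed = 43)
  samp <- scenario_phase_samples(sc, pairs = "LR_hind")
  band <- build_control_band(samp$folded_phase, pair = "LR_hind")
  cls <- classify_steps(samp, band)
  expect_lt(cls$n_altered / cls$n_total, 0.06)
})

test_that("empirical circular moments converge to scenario parameters", {
  sc <- gait_scenario(n_animals = 10, passes_per_animal = 10,
                      strides_per_pass = 10,
                      concentration = c(LR_fore = 10, LR_hind = 10,
                                        HLFL_ipsi = 10),
                      seed = 44)
  samp <- scenario_phase_samples(sc, pairs = "LR_hind")
  expect_gte(nrow(samp), 950)
  s <- circular_summary(samp$raw_phase)
  expect_lt(abs(s$mean_direction - 0.5), 0.01)
  A10 <- besselI(10, 1) / besselI(10, 0)
  expect_lt(abs(s$resultant_length - A10), 0.02)
})

test_that("angle traces reproduce imposed amplitudes and lags", {
  cycles <- data.frame(start_contact = c(0, 0.5),
                       stride_duration = c(0.5, 0.5),
                       stance_duration = c(0.3, 0.3))
  traces <- simulate_angle_traces(cycles, lag = 0.12)
  rom <- range_of_motion(traces[[1]])
  expect_equal(rom$excursion_deg[rom$angle == "proximal"], 40,
               tolerance = 0.5)
  expect_equal(rom$excursion_deg[rom$angle == "distal"], 70,
               tolerance = 0.5)
  expect_equal(peak_timing_phase(traces[[1]], 0.5), 0.12,
               tolerance = 1 / (200 * 0.5))
  # zero lag is in-phase; proximal peak sits at end of stance
  tr0 <- simulate_angle_traces(cycles, lag = 0)[[1]]
  expect_equal(peak_timing_phase(tr0, 0.5), 0, tolerance = 0.011)
  tpk <- tr0$time[which.max(tr0$proximal_deg)]
  expect_equal(tpk, 0.3, tolerance = 1 / 200 + 1e-9)
  expect_error(simulate_angle_traces(cycles,
                                     amplitudes = c(proximal = -1,
                                                    distal = 35)),
               "positive")
})

test_that("presets cover the study conditions", {
  ps <- scenario_presets()
  expect_setequal(names(ps), c("control_overground", "lapn_silenced",
                               "treadmill", "exploratory", "swim"))
  expect_error(scenario_presets("gallop_only"), "unknown preset")

  # swim generates no forelimb events and downstream skips gracefully
  swim <- simulate_pass(scenario_presets("swim", seed = 4))
  expect_null(swim$series$LF)
  expect_null(swim$series$RF)
  samp <- scenario_phase_samples(scenario_presets("swim", seed = 4),
                                 pairs = c("LR_hind", "LR_fore"))
  expect_true(all(samp$pair == "LR_hind"))

  # the silenced preset produces a detectably larger altered fraction
  ctrl <- scenario_phase_samples(
    scenario_presets("control_overground", seed = 5), pairs = "LR_hind")
  dox <- scenario_phase_samples(
    scenario_presets("lapn_silenced", seed = 5), pairs = "LR_hind")
  band <- build_control_band(ctrl$folded_phase, pair = "LR_hind")
  a1 <- classify_steps(ctrl, band)
  a2 <- classify_steps(dox, band)
  cmp <- two_proportion_z(a1$n_altered, a1$n_total,
                          a2$n_altered, a2$n_total)
  expect_gt(abs(cmp$z), 1.96)
  expect_gt(a2$n_altered / a2$n_total, a1$n_altered / a1$n_total)
})

test_that("control preset steps mostly classify as walk-trot", {
  sc <- scenario_presets("control_overground", seed = 6)
  sim <- simulate_scenario(sc)
  hind <- scenario_phase_samples(sc, pairs = "LR_hind", sim = sim)
  fore <- scenario_phase_samples(sc, pairs = "LR_fore", sim = sim)
  n <- min(nrow(hind), nrow(fore))
  labs <- classify_gait(hind$folded_phase[seq_len(n)],
                        fore$folded_phase[seq_len(n)])
  expect_gt(mean(labs == "walk_trot"), 0.95)
})
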