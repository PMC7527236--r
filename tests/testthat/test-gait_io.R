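test_that("event table round-trips through CSV and validates interleaving", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "animal,timepoint,pass,limb,event_type,time_s",
    "a1,baseline,p1,RH,contact,0.0",
    "a1,baseline,p1,RH,lift,0.3",
    "a1,baseline,p1,RH,contact,0.5"
  ), path)
  series <- read_event_table(path)
  expect_length(series, 1)
  s <- series[[1]]
  expect_equal(s$contacts, c(0, 0.5))
  expect_equal(s$lifts, 0.3)

  # lift before any contact violates interleaving, error names the pass
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "animal,timepoint,pass,limb,event_type,time_s",
    "a1,baseline,p7,RH,lift,0.1",
    "a1,baseline,p7,RH,contact,0.2"
  ), bad)
  expect_error(read_event_table(bad), "interleav.*p7|p7.*interleav")

  # missing required column is a schema error
  noc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,timepoint,pass,limb,time_s",
               "a1,baseline,p1,RH,0.0"), noc)
  expect_error(read_event_table(noc), "missing required column")

  # write -> read reproduces a synthetic bout exactly
  sim <- simulate_pass(scenario_presets("control_overground", seed = 3))
  out <- withr::local_tempfile(fileext = ".csv")
  write_event_table(sim$series, out)
  back <- read_event_table(out)
  orig <- sim$series[order(names(sim$series))]
  back <- back[order(vapply(back, `[[`, character(1), "limb"))]
  orig <- orig[order(vapply(orig, `[[`, character(1), "limb"))]
  for (i in seq_along(orig)) {
    expect_equal(back[[i]]$contacts, orig[[i]]$contacts, tolerance = 1e-9)
    expect_equal(back[[i]]$lifts, orig[[i]]$lifts, tolerance = 1e-9)
    expect_identical(back[[i]]$limb, orig[[i]]$limb)
  }
})

test_that("step-cycle extraction does the stated stance/swing arithmetic", {
  s <- make_series(c(0, 0.5, 1.0), c(0.3, 0.8))
  cy <- extract_step_cycles(s)
  expect_equal(nrow(cy), 2)
  expect_equal(cy$stride_duration, c(0.5, 0.5))
  expect_equal(cy$stance_duration, c(0.3, 0.3))
  expect_equal(cy$swing_duration, c(0.2, 0.2))
  expect_equal(cy$frequency_hz, c(2, 2))
  # stance + swing = stride exactly for event-derived cycles
  expect_equal(cy$stance_duration + cy$swing_duration, cy$stride_duration)

  # one complete cycle from two contacts; terminal partials dropped
  expect_equal(nrow(extract_step_cycles(make_series(c(0, 0.5), 0.3))), 1)
  # < 2 contacts: empty, not an error
  expect_equal(nrow(extract_step_cycles(make_series(0.1))), 0)
  expect_equal(nrow(extract_step_cycles(make_series(numeric(0)))), 0)
})

test_that("cycle count equals contacts - 1 and survives time translation", {
  sc <- scenario_presets("control_overground", seed = 11)
  sim <- simulate_pass(sc, 2, 3)
  s <- sim$series$RH
  cy <- extract_step_cycles(s)
  expect_equal(nrow(cy), length(s$contacts) - 1)

  shifted <- limb_event_series(s$animal_id, s$timepoint, s$pass_id,
                               s$limb, s$contacts + 7.5, s$lifts + 7.5,
                               task = s$task, surface = s$surface)
  cy2 <- extract_step_cycles(shifted)
  expect_equal(cy2$stride_duration, cy$stride_duration)
  expect_equal(cy2$stance_duration, cy$stance_duration)
})

test_that("duty cycle of generated bouts matches the generator setting", {
  sc <- gait_scenario(speed_range = c(40, 40),
                      duty_cycle_fn = function(v) 0.6,
                      stride_time_fn = function(v) 0.25,  # 4 Hz
                      stride_time_cv = 0, seed = 5)
  cy <- extract_step_cycles(simulate_pass(sc)$series$RH)
  expect_equal(mean(cy$stance_duration / cy$stride_duration), 0.60,
               tolerance = 1e-6)
  expect_equal(mean(cy$frequency_hz), 4, tolerance = 1e-6)
})

test_that("speed is marker displacement over stride duration", {
  s <- make_series(c(0, 0.5), 0.3)
  cy <- extract_step_cycles(s, body_track = make_linear_track(30, 1),
                            paw_track = make_linear_track(30, 1, marker = "paw"))
  expect_equal(cy$speed_cm_s, 30, tolerance = 1e-9)
  expect_equal(cy$stride_length_cm, 15, tolerance = 1e-9)

  # stationary marker -> zero speed
  still <- marker_track("groin", 100, x = rep(2, 101), y = rep(5, 101))
  cy0 <- extract_step_cycles(s, body_track = still)
  expect_equal(cy0$speed_cm_s, 0)

  # track gap inside the stride interval is a missing-data error
  short <- make_linear_track(30, 0.3)
  expect_error(extract_step_cycles(s, body_track = short), "span")
})

test_that("generated pass speed is recovered from markers within 2%", {
  sc <- gait_scenario(speed_range = c(80, 80), seed = 9)
  sim <- simulate_pass(sc)
  cy <- extract_step_cycles(sim$series$RH, body_track = sim$markers$body,
                            paw_track = sim$markers$paw_RH)
  expect_equal(mean(cy$speed_cm_s), 80, tolerance = 0.02)
  # stride length consistent with speed * stride duration
  expect_equal(cy$stride_length_cm,
               cy$speed_cm_s * cy$stride_duration, tolerance = 0.05)
})

test_that("marker tables round-trip through CSV", {
  sc <- gait_scenario(n_animals = 1, passes_per_animal = 1,
                      strides_per_pass = 4, seed = 2)
  dir <- withr::local_tempdir()
  simulate_to_dir(sc, dir)
  expect_true(all(file.exists(file.path(
    dir, c("events.csv", "markers.csv", "scenario.yaml")))))
  mk <- read_marker_table(file.path(dir, "markers.csv"), frame_rate = 200)
  tr <- mk[["A01"]][["P01"]][["groin"]]
  expect_s3_class(tr, "marker_track")
  orig <- simulate_pass(sc)$markers$body
  expect_equal(tr$x, orig$x, tolerance = 1e-6)
})
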