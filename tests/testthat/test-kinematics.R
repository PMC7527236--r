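mk_track <- function(name, xy, frame_rate = 100) {
  marker_track(name, frame_rate, x = xy[, 1], y = xy[, 2])
}

test_that("joint angles match the arccos dot-product oracle", {
  # static geometry held for 3 frames
  pts <- list(
    iliac_crest = c(0, 2), hip = c(0, 0), ankle = c(1.5, -1),
    toe = c(2.5, -0.5)
  )
  markers <- lapply(names(pts), function(m)
    mk_track(m, matrix(rep(pts[[m]], 3), ncol = 2, byrow = TRUE)))
  names(markers) <- names(pts)
  tr <- joint_angles(markers, 0, 0.02)
  ang <- function(a, v, b) {
    u <- a - v; w <- b - v
    acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
  }
  expect_equal(tr$proximal_deg,
               rep(ang(pts$iliac_crest, pts$hip, pts$ankle), 3),
               tolerance = 1e-9)
  expect_equal(tr$distal_deg,
               rep(ang(pts$hip, pts$ankle, pts$toe), 3),
               tolerance = 1e-9)

  # collinear three points: 180 degrees; right angle: 90 degrees
  col <- list(iliac_crest = c(0, 2), hip = c(0, 1), ankle = c(0, 0),
              toe = c(3, 0))
  mcol <- lapply(names(col), function(m)
    mk_track(m, matrix(rep(col[[m]], 2), ncol = 2, byrow = TRUE)))
  names(mcol) <- names(col)
  tr2 <- joint_angles(mcol, 0, 0.01)
  expect_equal(tr2$proximal_deg, rep(180, 2), tolerance = 1e-9)
  expect_equal(tr2$distal_deg, rep(90, 2), tolerance = 1e-9)
})

test_that("all angle operations are invariant under rigid transforms", {
  pts <- list(iliac_crest = c(0.3, 2.1), hip = c(0.1, 0.2),
              ankle = c(1.4, -0.9), toe = c(2.2, -0.4))
  ang0 <- {
    m <- lapply(names(pts), function(m)
      mk_track(m, matrix(rep(pts[[m]], 2), ncol = 2, byrow = TRUE)))
    names(m) <- names(pts)
    joint_angles(m, 0, 0.01)
  }
  for (theta in c(0.4, 2.1)) {
    shift <- c(3.2, -1.1)
    scale <- 2.5
    tpts <- lapply(pts, function(p) scale * rotate2(p, theta) + shift)
    m <- lapply(names(tpts), function(m)
      mk_track(m, matrix(rep(tpts[[m]], 2), ncol = 2, byrow = TRUE)))
    names(m) <- names(tpts)
    tr <- joint_angles(m, 0, 0.01)
    expect_equal(tr$proximal_deg, ang0$proximal_deg, tolerance = 1e-9)
    expect_equal(tr$distal_deg, ang0$distal_deg, tolerance = 1e-9)
  }

  # base of support and trunk angle under the same transforms
  bos0 <- base_of_support_angle(c(0, 10), c(0, 0), c(2, -3))
  ta0 <- trunk_angle(c(0, 0), c(10, 0), c(2, 3), c(5, 5))
  for (theta in c(0.7, -1.2)) {
    sh <- c(-2, 4)
    expect_equal(
      base_of_support_angle(rotate2(c(0, 10), theta) + sh,
                            rotate2(c(0, 0), theta) + sh,
                            rotate2(c(2, -3), theta) + sh),
      bos0, tolerance = 1e-9)
    expect_equal(
      trunk_angle(rotate2(c(0, 0), theta) + sh,
                  rotate2(c(10, 0), theta) + sh,
                  rotate2(c(2, 3), theta) + sh,
                  rotate2(c(5, 5), theta) + sh),
      ta0, tolerance = 1e-9)
  }
})

test_that("range of motion recovers excursions and degenerate cases", {
  tt <- seq(0, 0.5, by = 0.005)
  tr <- data.frame(time = tt,
                   proximal_deg = 110 + 20 * cos(2 * pi * tt / 0.5),
                   distal_deg = 90 + 35 * sin(2 * pi * tt / 0.5))
  class(tr) <- c("angle_trace", "data.frame")
  rom <- range_of_motion(tr)
  expect_equal(rom$excursion_deg[rom$angle == "proximal"], 40,
               tolerance = 0.1)
  expect_equal(rom$excursion_deg[rom$angle == "distal"], 70,
               tolerance = 0.1)
  expect_true(all(rom$excursion_deg >= 0))

  flat <- data.frame(time = tt, proximal_deg = 100, distal_deg = 90)
  class(flat) <- c("angle_trace", "data.frame")
  expect_equal(range_of_motion(flat)$excursion_deg, c(0, 0))
  expect_error(range_of_motion(flat[1, ]), "at least 2")
})

test_that("peak-timing phase measures the proximal-to-distal lag", {
  tt <- seq(0, 0.5, by = 0.0025)
  mk <- function(lag) {
    tr <- data.frame(
      time = tt,
      proximal_deg = 110 + 20 * cos(2 * pi * (tt / 0.5 - 0.6)),
      distal_deg = 90 + 35 * cos(2 * pi * (tt / 0.5 - 0.6 - lag))
    )
    class(tr) <- c("angle_trace", "data.frame")
    tr
  }
  expect_equal(peak_timing_phase(mk(0), 0.5), 0, tolerance = 0.01)
  expect_equal(peak_timing_phase(mk(0.5), 0.5), 0.5, tolerance = 0.01)
  expect_equal(peak_timing_phase(mk(0.12), 0.5), 0.12, tolerance = 0.01)
  # a trace against itself is in phase
  tr <- mk(0)
  tr$distal_deg <- tr$proximal_deg
  expect_equal(peak_timing_phase(tr, 0.5), 0)
  flat <- mk(0)
  flat$proximal_deg <- 100
  expect_error(peak_timing_phase(flat, 0.5), "flat")
})

test_that("base-of-support angle reads paw rotation off the body axis", {
  # shoulders above groin, body axis pointing down (caudal = -y)
  expect_equal(base_of_support_angle(c(0, 10), c(0, 0), c(0, -5)), 0,
               tolerance = 1e-9)
  expect_equal(base_of_support_angle(c(0, 10), c(0, 0), c(4, 0)), 90,
               tolerance = 1e-9)
  # constructed 30 degree external rotation
  paw <- c(sin(pi / 6), -cos(pi / 6)) * 3
  expect_equal(base_of_support_angle(c(0, 10), c(0, 0), paw), 30,
               tolerance = 1e-9)
  expect_error(base_of_support_angle(c(0, 0), c(0, 0), c(1, 1)),
               "coincident")
})

test_that("trunk angle is the acute angle to the water surface", {
  expect_equal(trunk_angle(c(0, 0), c(10, 0), c(1, 2), c(4, 2)), 0,
               tolerance = 1e-9)
  expect_equal(trunk_angle(c(0, 0), c(10, 0), c(0, 0), c(3, 3)), 45,
               tolerance = 1e-9)
  # obtuse configurations report the acute angle
  expect_equal(trunk_angle(c(0, 0), c(10, 0), c(3, 3), c(0, 0)), 45,
               tolerance = 1e-9)
  expect_error(trunk_angle(c(0, 0), c(0, 0), c(1, 1), c(2, 2)),
               "degenerate")

  strokes <- data.frame(start = c(0, 0.5), end = c(0.5, 1))
  tt <- seq(0, 1, by = 0.01)
  markers <- list(
    iliac_crest = marker_track("iliac_crest", 100, x = tt * 0, y = tt * 0),
    hip = marker_track("hip", 100, x = rep(3, length(tt)),
                       y = rep(3, length(tt)))
  )
  angs <- stroke_trunk_angles(markers, c(0, 0), c(10, 0), strokes)
  expect_equal(angs, c(45, 45), tolerance = 1e-9)
})
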