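#' Draw circular phases from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler, with phases expressed on the
#' unit interval (one cycle = 1). kappa = 0 gives the circular uniform;
#' kappa = Inf gives the point mass at the mean.
#'
#' @param n number of draws.
#' @param mean_phase circular mean in [0, 1).
#' @param kappa concentration parameter (>= 0).
#' @return numeric vector of phases in [0, 1).
#' @export
rvonmises_phase <- function(n, mean_phase, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 0) stop("kappa must be >= 0")
  mu <- 2 * pi * (mean_phase %% 1)
  if (kappa == 0) return(stats::runif(n))
  if (!is.finite(kappa)) return(rep(mean_phase %% 1, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      i <- i + 1L
      out[i] <- (mu + sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))) %%
        (2 * pi)
    }
  }
  out / (2 * pi)
}

#' Synthetic gait scenario
#'
#' Parameter bundle for the seeded gait generator. Defaults emulate
#' volitional overground walk-trot stepping of the adult rat: per-pass
#' speeds drawn uniformly on \code{speed_range}; stride time following a
#' decreasing power law of speed (t = 0.8 v^-0.55 s with v in cm/s, with
#' multiplicative log-normal noise); duty cycle falling linearly from
#' 0.70 at 20 cm/s to 0.45 at 120 cm/s; left-right coupling at each
#' girdle concentrated (von Mises) around alternation (0.5) and the
#' homolateral hindlimb-forelimb pair around 0.5, with the diagonal pair
#' in-phase by construction. A fraction \code{disruption_rate} of
#' strides has its left-limb phases redrawn (uniformly on the circle, or
#' shifted by 0.25) to emulate decoupled stepping.
#'
#' @param n_animals,passes_per_animal,strides_per_pass cohort shape; the
#'   default 6 x 8 x 10 yields 480 reference strides.
#' @param speed_range pass speed range, cm/s.
#' @param pair_phase_means named circular means in [0, 1) for
#'   \code{LR_fore}, \code{LR_hind}, \code{HLFL_ipsi}.
#' @param concentration named von Mises kappa per pair.
#' @param duty_cycle_fn,stride_time_fn functions of speed (cm/s).
#' @param stride_time_cv log-scale SD of stride-time noise.
#' @param disruption_rate per-stride probability of a decoupled step.
#' @param disruption_mode "uniform_phase" or "shifted_phase".
#' @param timepoint,task,surface labels stamped on the generated series.
#' @param hindlimb_only generate no forelimb events (swimming).
#' @param frame_rate marker sampling rate, Hz.
#' @param seed integer master seed; per-pass substreams are derived from
#'   it deterministically.
#' @return object of class \code{gait_scenario} (a validated list).
#' @export
gait_scenario <- function(n_animals = 6,
                          passes_per_animal = 8,
                          strides_per_pass = 10,
                          speed_range = c(20, 90),
                          pair_phase_means = c(LR_fore = 0.5,
                                               LR_hind = 0.5,
                                               HLFL_ipsi = 0.5),
                          concentration = c(LR_fore = 12,
                                            LR_hind = 12,
                                            HLFL_ipsi = 14),
                          duty_cycle_fn = default_duty_cycle,
                          stride_time_fn = default_stride_time,
                          stride_time_cv = 0.05,
                          disruption_rate = 0,
                          disruption_mode = c("uniform_phase",
                                              "shifted_phase"),
                          timepoint = "baseline",
                          task = "overground",
                          surface = "coated",
                          hindlimb_only = FALSE,
                          frame_rate = 200,
                          seed = 1) {
  disruption_mode <- match.arg(disruption_mode)
  if (disruption_rate < 0 || disruption_rate > 1) {
    stop("disruption_rate must lie in [0, 1]")
  }
  v <- seq(speed_range[1], speed_range[2], length.out = 25)
  st <- vapply(v, stride_time_fn, numeric(1))
  if (any(st <= 0)) stop("stride_time_fn must be positive on speed_range")
  if (any(diff(st) > 1e-9)) {
    stop("stride_time_fn must be decreasing on speed_range")
  }
  dc <- vapply(v, duty_cycle_fn, numeric(1))
  if (any(dc <= 0 | dc >= 1)) {
    stop("duty cycle must lie in (0, 1) on speed_range")
  }
  structure(
    list(n_animals = n_animals, passes_per_animal = passes_per_animal,
         strides_per_pass = strides_per_pass, speed_range = speed_range,
         pair_phase_means = pair_phase_means,
         concentration = concentration,
         duty_cycle_fn = duty_cycle_fn, stride_time_fn = stride_time_fn,
         stride_time_cv = stride_time_cv,
         disruption_rate = disruption_rate,
         disruption_mode = disruption_mode,
         timepoint = timepoint, task = task, surface = surface,
         hindlimb_only = hindlimb_only,
         frame_rate = frame_rate, seed = as.integer(seed)),
    class = "gait_scenario"
  )
}

#' @rdname gait_scenario
#' @param speed speed in cm/s.
#' @export
default_stride_time <- function(speed) 2.6 * speed^(-0.55)

#' @rdname gait_scenario
#' @export
default_duty_cycle <- function(speed) {
  pmin(0.8, pmax(0.3, 0.70 - 0.25 * (speed - 20) / 100))
}

pass_seed <- function(scenario, animal_idx, pass_idx) {
  (scenario$seed %% 100000L) * 10007L + animal_idx * 211L + pass_idx
}

#' Simulate one locomotor pass
#'
#' Generates the four limb event series and marker tracks for one pass.
#' The right hindlimb is the reference: its contacts accumulate the
#' stride times; the left hindlimb is offset by von Mises draws around
#' the left-right hindlimb mean, the right forelimb by draws around the
#' homolateral (ipsi) hindlimb-forelimb mean, and the left forelimb is
#' placed relative to the right forelimb using the left-right forelimb
#' mean (so the diagonal pair is in-phase by composition). With
#' probability \code{disruption_rate} a stride's left-limb phases are
#' redrawn per \code{disruption_mode}. All limbs produce the same number
#' of contacts, so generated passes step in a strict 1:1 ratio.
#' Deterministic given the scenario seed and indices.
#'
#' @param scenario a \code{gait_scenario}.
#' @param animal_idx,pass_idx 1-based indices used for labelling and for
#'   the deterministic per-pass RNG substream.
#' @return list with \code{series} (named list LF/RF/LH/RH of
#'   \code{limb_event_series}; forelimbs absent when
#'   \code{hindlimb_only}), \code{markers} (body and per-paw
#'   \code{marker_track}s), \code{speed_cm_s} and \code{n_disrupted}.
#' @export
simulate_pass <- function(scenario, animal_idx = 1, pass_idx = 1) {
  stopifnot(inherits(scenario, "gait_scenario"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(pass_seed(scenario, animal_idx, pass_idx))

  n <- scenario$strides_per_pass
  v <- stats::runif(1, scenario$speed_range[1], scenario$speed_range[2])
  duty <- scenario$duty_cycle_fn(v)
  t_base <- scenario$stride_time_fn(v)
  stride_t <- t_base * exp(stats::rnorm(n + 1, 0, scenario$stride_time_cv))
  rh_contacts <- 0.2 + cumsum(c(0, stride_t[seq_len(n)]))  # n + 1 contacts
  # per-contact stride scale (last contact reuses the trailing draw)
  scale_t <- c(stride_t[seq_len(n)], stride_t[n + 1])

  means <- scenario$pair_phase_means
  kap <- scenario$concentration
  ph_lh <- rvonmises_phase(n + 1, means[["LR_hind"]], kap[["LR_hind"]])
  disrupted <- stats::runif(n + 1) < scenario$disruption_rate
  redraw <- function(ph) {
    if (scenario$disruption_mode == "uniform_phase") {
      stats::runif(length(ph))
    } else {
      (ph + 0.25) %% 1
    }
  }
  ph_lh[disrupted] <- redraw(ph_lh[disrupted])
  lh_contacts <- sort(rh_contacts + ph_lh * scale_t)

  mk_series <- function(limb, contacts) {
    nct <- length(contacts)
    lifts <- contacts[-nct] + duty * diff(contacts)
    limb_event_series(
      animal_id = sprintf("A%02d", animal_idx),
      timepoint = scenario$timepoint,
      pass_id = sprintf("P%02d", pass_idx),
      limb = limb, contacts = contacts, lifts = lifts,
      task = scenario$task, surface = scenario$surface
    )
  }

  series <- list(RH = mk_series("RH", rh_contacts),
                 LH = mk_series("LH", lh_contacts))
  if (!scenario$hindlimb_only) {
    ph_rf <- rvonmises_phase(n + 1, means[["HLFL_ipsi"]],
                             kap[["HLFL_ipsi"]])
    rf_contacts <- sort(rh_contacts + ph_rf * scale_t)
    ph_lf <- rvonmises_phase(n + 1, means[["LR_fore"]], kap[["LR_fore"]])
    ph_lf[disrupted] <- redraw(ph_lf[disrupted])
    lf_contacts <- sort(rf_contacts + ph_lf * scale_t)
    series$RF <- mk_series("RF", rf_contacts)
    series$LF <- mk_series("LF", lf_contacts)
  }

  t_end <- max(vapply(series, function(s)
    max(c(s$contacts, s$lifts)), numeric(1))) + 0.2
  frames <- seq(0, t_end, by = 1 / scenario$frame_rate)
  markers <- list(
    body = marker_track("groin", scenario$frame_rate,
                        x = v * frames, y = rep(5, length(frames)))
  )
  for (limb in names(series)) {
    s <- series[[limb]]
    nct <- length(s$contacts)
    # paw holds its plant position through stance, advances during swing
    kt <- c(0, as.vector(rbind(s$contacts, c(s$lifts, t_end))), t_end + 1)
    kx <- c(v * s$contacts[1],
            as.vector(rbind(v * s$contacts, v * s$contacts)),
            v * s$contacts[nct])
    o <- order(kt)
    paw_x <- stats::approx(kt[o], kx[o], xout = frames, rule = 2,
                           ties = "ordered")$y
    markers[[paste0("paw_", limb)]] <-
      marker_track(paste0("paw_", limb), scenario$frame_rate,
                   x = paw_x, y = rep(1, length(frames)))
  }

  list(series = series, markers = markers, speed_cm_s = v,
       n_disrupted = sum(disrupted))
}

#' Simulate a full scenario
#'
#' Runs \code{\link{simulate_pass}} over every animal and pass of a
#' scenario.
#'
#' @param scenario a \code{gait_scenario}.
#' @return list of passes, each as returned by \code{simulate_pass},
#'   named "A<animal>_P<pass>".
#' @export
simulate_scenario <- function(scenario) {
  out <- list()
  for (a in seq_len(scenario$n_animals)) {
    for (p in seq_len(scenario$passes_per_animal)) {
      out[[sprintf("A%02d_P%02d", a, p)]] <- simulate_pass(scenario, a, p)
    }
  }
  out
}

#' Phase samples for all passes of a simulated scenario
#'
#' Convenience wrapper: simulates the scenario and computes interlimb
#' phase samples for the requested limb pairs (reference right limbs),
#' carrying stride speed from the body marker.
#'
#' @param scenario a \code{gait_scenario}.
#' @param pairs subset of \code{c("LR_hind", "LR_fore", "HLFL_ipsi",
#'   "HLFL_contra")}.
#' @param sim optional pre-computed result of
#'   \code{\link{simulate_scenario}}.
#' @return phase-sample data.frame (see
#'   \code{\link{pair_phase_samples}}).
#' @export
scenario_phase_samples <- function(scenario,
                                   pairs = c("LR_hind", "LR_fore"),
                                   sim = NULL) {
  if (is.null(sim)) sim <- simulate_scenario(scenario)
  ref_of <- c(LR_hind = "RH", LR_fore = "RF",
              HLFL_ipsi = "RH", HLFL_contra = "RH")
  paired_of <- c(LR_hind = "LH", LR_fore = "LF",
                 HLFL_ipsi = "RF", HLFL_contra = "LF")
  rows <- list()
  for (ps in sim) {
    for (pr in pairs) {
      ref <- ps$series[[ref_of[[pr]]]]
      paired <- ps$series[[paired_of[[pr]]]]
      if (is.null(ref) || is.null(paired)) next
      rows[[length(rows) + 1L]] <-
        pair_phase_samples(ref, paired, pr, body_track = ps$markers$body)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic intralimb angle traces for simulated strides
#'
#' Smooth periodic proximal and distal joint-angle traces for each
#' stride, with peaks placed at the end of stance (the canonical timing
#' just before lift-off) and a configurable distal-after-proximal lag.
#'
#' @param cycles \code{step_cycles} data.frame.
#' @param amplitudes named numeric, half-excursion in degrees for
#'   \code{proximal} and \code{distal} (excursion = 2 x amplitude).
#' @param base named numeric, mean angles in degrees.
#' @param lag distal-minus-proximal peak lag as a fraction of the stride.
#' @param duty stance fraction used to place the proximal peak.
#' @param frame_rate sampling rate in Hz.
#' @return list of \code{angle_trace} objects, one per stride.
#' @export
simulate_angle_traces <- function(cycles,
                                  amplitudes = c(proximal = 20,
                                                 distal = 35),
                                  base = c(proximal = 110, distal = 90),
                                  lag = 0, duty = 0.6,
                                  frame_rate = 200) {
  if (any(amplitudes <= 0)) stop("amplitudes must be positive")
  lapply(seq_len(nrow(cycles)), function(i) {
    t0 <- cycles$start_contact[i]
    Tt <- cycles$stride_duration[i]
    peak_prox <- if ("stance_duration" %in% names(cycles) &&
                     !is.na(cycles$stance_duration[i])) {
      cycles$stance_duration[i] / Tt
    } else duty
    tt <- seq(t0, t0 + Tt, by = 1 / frame_rate)
    phase <- (tt - t0) / Tt
    out <- data.frame(
      time = tt,
      proximal_deg = base[["proximal"]] + amplitudes[["proximal"]] *
        cos(2 * pi * (phase - peak_prox)),
      distal_deg = base[["distal"]] + amplitudes[["distal"]] *
        cos(2 * pi * (phase - peak_prox - lag))
    )
    class(out) <- c("angle_trace", "data.frame")
    attr(out, "stride_id") <- sprintf("stride_%03d", i)
    out
  })
}

#' Named scenario presets
#'
#' Fixed parameterisations emulating the study conditions:
#' \describe{
#'   \item{control_overground}{alternating walk-trot, low phase
#'     dispersion, near-zero disruption.}
#'   \item{lapn_silenced}{elevated left-right dispersion and a 0.25
#'     per-stride decoupling rate at each girdle, with the stride-speed
#'     laws left intact.}
#'   \item{treadmill}{silenced condition on the treadmill: narrower
#'     speed range and a smaller decoupling rate.}
#'   \item{exploratory}{silenced condition during exploratory stepping:
#'     tight alternation, near-zero disruption.}
#'   \item{swim}{hindlimb-only alternation (no forelimb events).}
#' }
#'
#' @param name preset name; \code{NULL} lists all presets.
#' @param seed master seed stored in the returned scenario(s).
#' @return a \code{gait_scenario}, or a named list of them.
#' @export
scenario_presets <- function(name = NULL, seed = 1) {
  presets <- list(
    control_overground = gait_scenario(
      disruption_rate = 0.01, timepoint = "baseline", seed = seed),
    lapn_silenced = gait_scenario(
      concentration = c(LR_fore = 4, LR_hind = 4, HLFL_ipsi = 14),
      disruption_rate = 0.25, timepoint = "dox_on",
      passes_per_animal = 10, seed = seed),
    treadmill = gait_scenario(
      speed_range = c(20, 60), disruption_rate = 0.15,
      concentration = c(LR_fore = 6, LR_hind = 6, HLFL_ipsi = 14),
      timepoint = "dox_on", task = "treadmill", seed = seed),
    exploratory = gait_scenario(
      concentration = c(LR_fore = 16, LR_hind = 14, HLFL_ipsi = 18),
      disruption_rate = 0.005, timepoint = "dox_on",
      task = "exploratory", seed = seed),
    swim = gait_scenario(
      pair_phase_means = c(LR_fore = 0.5, LR_hind = 0.5,
                           HLFL_ipsi = 0.5),
      concentration = c(LR_fore = 12, LR_hind = 12, HLFL_ipsi = 12),
      hindlimb_only = TRUE, task = "swim", timepoint = "baseline",
      seed = seed)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

#' Write a simulated scenario to CSV files
#'
#' Emits \code{events.csv} (long-format footfall events),
#' \code{markers.csv} (body and paw tracks) and \code{scenario.yaml}
#' (the scalar scenario parameters) into a directory.
#'
#' @param scenario a \code{gait_scenario}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
simulate_to_dir <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_scenario(scenario)
  all_series <- unlist(lapply(sim, `[[`, "series"), recursive = FALSE)
  write_event_table(all_series, file.path(dir, "events.csv"))
  mk_rows <- lapply(names(sim), function(nm) {
    ps <- sim[[nm]]
    do.call(rbind, lapply(ps$markers, function(tr) {
      data.frame(animal = ps$series$RH$animal_id,
                 pass = ps$series$RH$pass_id,
                 frame = seq_along(tr$x) - 1L,
                 marker = tr$marker, x_cm = tr$x, y_cm = tr$y,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, mk_rows),
                   file.path(dir, "markers.csv"), row.names = FALSE,
                   quote = FALSE)
  scal <- list(
    n_animals = scenario$n_animals,
    passes_per_animal = scenario$passes_per_animal,
    strides_per_pass = scenario$strides_per_pass,
    speed_range = scenario$speed_range,
    pair_phase_means = as.list(scenario$pair_phase_means),
    concentration = as.list(scenario$concentration),
    disruption_rate = scenario$disruption_rate,
    disruption_mode = scenario$disruption_mode,
    timepoint = scenario$timepoint, task = scenario$task,
    surface = scenario$surface, hindlimb_only = scenario$hindlimb_only,
    frame_rate = scenario$frame_rate, seed = scenario$seed
  )
  yaml::write_yaml(scal, file.path(dir, "scenario.yaml"))
  invisible(dir)
}
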