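pair_limbs <- function() {
  list(LR_hind = c(ref = "RH", paired = "LH"),
       LR_fore = c(ref = "RF", paired = "LF"),
       HLFL_ipsi = c(ref = "RH", paired = "RF"),
       HLFL_contra = c(ref = "RH", paired = "LF"))
}

#' Pipeline run configuration
#'
#' @param control_timepoints,dox_timepoints disjoint character vectors of
#'   timepoint labels; control passes pool into the variability bands.
#' @param k control band half-width in SD units.
#' @param freq_threshold_hz step-frequency threshold for the
#'   phase-frequency tabulation.
#' @param min_cycles minimum complete reference strides for a pass to
#'   enter the coordination analyses.
#' @param pairs limb pairs to analyse.
#' @param u2_n_perm permutations for the Watson U2 tests.
#' @param seed integer seed for all stochastic steps.
#' @return validated configuration list.
#' @export
run_config <- function(control_timepoints = c("baseline", "pre_dox",
                                              "dox_off"),
                       dox_timepoints = "dox_on",
                       k = 2, freq_threshold_hz = 5, min_cycles = 3,
                       pairs = c("LR_hind", "LR_fore", "HLFL_ipsi",
                                 "HLFL_contra"),
                       u2_n_perm = 2000, seed = 1) {
  if (length(intersect(control_timepoints, dox_timepoints))) {
    stop("control and dox timepoint label sets must be disjoint")
  }
  if (k <= 0) stop("k must be positive")
  pairs <- match.arg(pairs, several.ok = TRUE)
  list(control_timepoints = control_timepoints,
       dox_timepoints = dox_timepoints, k = k,
       freq_threshold_hz = freq_threshold_hz, min_cycles = min_cycles,
       pairs = pairs, u2_n_perm = u2_n_perm, seed = as.integer(seed))
}

#' Run the full coordination analysis pipeline
#'
#' From per-limb footfall series to phase samples, control bands,
#' altered-step classification, proportion tests, gait labels,
#' phase-frequency tabulation, Watson U2 comparisons and stepping
#' indices. Control timepoints pool into one band per limb pair and
#' task/surface; every sample from any timepoint is then classified
#' against its band, and altered-step proportions are compared between
#' the control and dox pools.
#'
#' @param series list of \code{limb_event_series} (e.g. from
#'   \code{\link{read_event_table}} or \code{\link{simulate_scenario}}),
#'   or a long-format events data.frame.
#' @param config from \code{\link{run_config}}.
#' @param markers optional nested list of \code{marker_track}s by animal
#'   then pass then marker name (see \code{\link{read_marker_table}});
#'   when present, phases carry stride speed from the \code{groin} body
#'   marker.
#' @param out_dir optional directory; when given, writes
#'   \code{phases.csv}, \code{comparisons.csv}, \code{band.yaml},
#'   \code{u2_results.json} and \code{summary.md}.
#' @return list with \code{phases} (classified samples),
#'   \code{bands}, \code{comparisons}, \code{u2}, \code{phase_frequency},
#'   \code{stepping}, \code{config}.
#' @export
run_pipeline <- function(series, config = run_config(), markers = NULL,
                         out_dir = NULL) {
  if (is.data.frame(series)) series <- events_to_series(series)
  if (length(series) == 0) stop("stage read: no input series")

  # index series by (animal, timepoint, pass, limb)
  keys <- vapply(series, function(s)
    paste(s$animal_id, s$timepoint, s$pass_id, sep = "\r"), character(1))
  limbs <- vapply(series, `[[`, character(1), "limb")
  pl <- pair_limbs()

  body_track_for <- function(s) {
    if (is.null(markers)) return(NULL)
    m <- markers[[s$animal_id]][[s$pass_id]]
    m[["groin"]] %||% m[["body"]]
  }

  phase_rows <- list()
  step_counts <- list()
  for (key in unique(keys)) {
    grp <- series[keys == key]
    grp_limbs <- limbs[keys == key]
    names(grp) <- grp_limbs
    rh <- grp[["RH"]]
    # per-pass inclusion: enough complete reference strides
    ref_series <- grp[["RH"]] %||% grp[["RF"]]
    if (is.null(ref_series)) next
    n_ref <- max(0, length(ref_series$contacts) - 1)
    if (n_ref < config$min_cycles) next
    fore_n <- sum(vapply(grp[grp_limbs %in% c("LF", "RF")], function(s)
      max(0, length(s$contacts) - 1), numeric(1)))
    hind_n <- sum(vapply(grp[grp_limbs %in% c("LH", "RH")], function(s)
      max(0, length(s$contacts) - 1), numeric(1)))
    step_counts[[length(step_counts) + 1L]] <- data.frame(
      animal = ref_series$animal_id, timepoint = ref_series$timepoint,
      fore_cycles = fore_n, hind_cycles = hind_n,
      stringsAsFactors = FALSE
    )
    for (pr in config$pairs) {
      ref <- grp[[pl[[pr]][["ref"]]]]
      paired <- grp[[pl[[pr]][["paired"]]]]
      if (is.null(ref) || is.null(paired)) next
      phase_rows[[length(phase_rows) + 1L]] <-
        pair_phase_samples(ref, paired, pr,
                           body_track = body_track_for(ref))
    }
  }
  if (length(phase_rows) == 0) stop("stage phases: no analysable passes")
  phases <- do.call(rbind, phase_rows)
  rownames(phases) <- NULL
  phases$condition <- ifelse(
    phases$timepoint %in% config$control_timepoints, "control",
    ifelse(phases$timepoint %in% config$dox_timepoints, "dox", "other"))

  # control bands per pair x task x surface
  bands <- list()
  classified <- list()
  comparisons <- list()
  for (grp in split(phases,
                    interaction(phases$pair, phases$task, phases$surface,
                                drop = TRUE))) {
    pr <- grp$pair[1]
    ctrl <- grp[grp$condition == "control", ]
    if (nrow(ctrl) < 2) {
      warning("stage bands: no control pool for ", pr, " / ",
              grp$task[1], "; group skipped", call. = FALSE)
      next
    }
    band <- build_control_band(ctrl$folded_phase, k = config$k, pair = pr)
    bands[[paste(pr, grp$task[1], grp$surface[1], sep = ".")]] <- band
    cls <- classify_steps(grp, band)
    classified[[length(classified) + 1L]] <- cls$samples
    cc <- cls$samples[cls$samples$condition == "control", ]
    dd <- cls$samples[cls$samples$condition == "dox", ]
    if (nrow(cc) && nrow(dd)) {
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        pair = pr, task = grp$task[1], surface = grp$surface[1],
        x1 = sum(cc$altered), n1 = nrow(cc),
        x2 = sum(dd$altered), n2 = nrow(dd),
        stringsAsFactors = FALSE
      )
    }
  }
  phases <- do.call(rbind, classified)
  rownames(phases) <- NULL
  comparison_tab <- if (length(comparisons)) {
    proportion_report(do.call(rbind, comparisons))
  } else NULL

  # Watson U2 control vs dox per pair (raw phases)
  u2 <- list()
  for (pr in unique(phases$pair)) {
    cc <- phases$raw_phase[phases$pair == pr &
                             phases$condition == "control"]
    dd <- phases$raw_phase[phases$pair == pr & phases$condition == "dox"]
    if (length(cc) >= 4 && length(dd) >= 4) {
      u2[[pr]] <- watson_u2(cc, dd, n_perm = config$u2_n_perm,
                            seed = config$seed)
    }
  }

  pf <- phase_frequency_table(phases,
                              threshold_hz = config$freq_threshold_hz)

  steps <- do.call(rbind, step_counts)
  stepping <- do.call(rbind, lapply(
    split(steps, interaction(steps$animal,
                             steps$timepoint %in% config$control_timepoints,
                             drop = TRUE)),
    function(g) data.frame(
      animal = g$animal[1],
      condition = if (g$timepoint[1] %in% config$control_timepoints)
        "control" else "dox",
      fore_cycles = sum(g$fore_cycles), hind_cycles = sum(g$hind_cycles),
      stepping_index = if (sum(g$fore_cycles) > 0)
        stepping_index(sum(g$fore_cycles), sum(g$hind_cycles)) else NA_real_,
      stringsAsFactors = FALSE
    )))
  rownames(stepping) <- NULL

  result <- list(phases = phases, bands = bands,
                 comparisons = comparison_tab, u2 = u2,
                 phase_frequency = pf, stepping = stepping,
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(result$phases, file.path(out_dir, "phases.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(result$comparisons)) {
    utils::write.csv(result$comparisons,
                     file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(
    lapply(result$bands, function(b) b[c("pair", "mean_folded",
                                         "sd_folded", "lower", "upper",
                                         "k", "n")]),
    file.path(out_dir, "band.yaml")
  )
  jsonlite::write_json(
    lapply(result$u2, function(u)
      list(u2 = u$u2, n1 = u$n1, n2 = u$n2, p = u$p_value,
           method = u$method, seed = u$seed)),
    file.path(out_dir, "u2_results.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  md <- c("# Coordination analysis summary", "",
          sprintf("- phase samples: %d", nrow(result$phases)),
          sprintf("- altered steps: %d (%.2f%%)",
                  sum(result$phases$altered),
                  100 * mean(result$phases$altered)),
          sprintf("- mean stepping index: %.2f",
                  mean(result$stepping$stepping_index, na.rm = TRUE)))
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

#' Counts-only proportion comparison
#'
#' Entry point for pre-tabulated altered/total step counts, so printed
#' count tables can be compared without raw per-step data.
#'
#' @param x1,n1,x2,n2 altered and total counts for the two conditions.
#' @param pooled use the pooled standard error.
#' @return a \code{prop_comparison} (see
#'   \code{\link{two_proportion_z}}).
#' @examples
#' compare_counts(26, 480, 135, 600)
#' @export
compare_counts <- function(x1, n1, x2, n2, pooled = FALSE) {
  two_proportion_z(x1, n1, x2, n2, pooled = pooled)
}
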