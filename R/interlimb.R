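PAIRS <- c("LR_fore", "LR_hind", "HLFL_ipsi", "HLFL_contra")

#' Fold a circular phase onto the linear half-scale
#'
#' Interlimb phases on [0, 1) are mirror-symmetric in which limb happens
#' to lead: a left-lead gallop at 0.25 and a right-lead gallop at 0.75
#' are the same coupling pattern. Folding maps the circle onto [0.5, 1.0]
#' (x if x >= 0.5, else 1 - x) so mirror patterns coincide: 0.5 stays
#' alternation, 1.0 is synchrony. Folding is idempotent.
#'
#' @param x numeric vector of phases in [0, 1).
#' @return folded phases in [0.5, 1.0].
#' @examples
#' fold_phase(c(0.25, 0.75))  # both 0.75 (gallop)
#' @export
fold_phase <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("phases must lie in [0, 1]")
  ifelse(x >= 0.5, x, 1 - x)
}

#' Interlimb phase of one reference stride
#'
#' The coupling value of a limb pair for one reference stride: the
#' paired limb's first paw contact inside the half-open stride window
#' [start, start + stride), expressed as a fraction of the stride.
#' 0.5 is strict alternation, 0 (== 1 after folding) is synchrony.
#'
#' @param reference_cycle one row of a \code{step_cycles} table.
#' @param paired_series \code{limb_event_series} of the paired limb.
#' @return list with \code{raw_phase}, \code{folded_phase},
#'   \code{frequency_hz}, or \code{NULL} when the paired limb made no
#'   contact in the window (a 1:1-stepping violation, counted by the
#'   stepping index, not an error).
#' @export
compute_phase <- function(reference_cycle, paired_series) {
  t0 <- reference_cycle$start_contact
  t1 <- t0 + reference_cycle$stride_duration
  pc <- paired_series$contacts
  hit <- pc[pc >= t0 & pc < t1]
  if (length(hit) == 0L) return(NULL)
  raw <- (hit[1] - t0) / reference_cycle$stride_duration
  list(raw_phase = raw, folded_phase = fold_phase(raw),
       frequency_hz = 1 / reference_cycle$stride_duration)
}

#' Phase samples for a limb pair over a whole pass
#'
#' Applies \code{\link{compute_phase}} to every complete stride of the
#' reference limb. Strides without a paired contact are skipped and
#' counted in the \code{n_skipped} attribute.
#'
#' @param reference_series \code{limb_event_series} of the reference limb
#'   (by convention the right limb of the pair).
#' @param paired_series \code{limb_event_series} of the paired limb.
#' @param pair pair label: "LR_fore", "LR_hind", "HLFL_ipsi" or
#'   "HLFL_contra".
#' @param body_track optional body \code{marker_track}; when given each
#'   sample carries the stride speed.
#' @return data.frame of phase samples: animal, timepoint, task, surface,
#'   pass, pair, raw_phase, folded_phase, frequency_hz, speed_cm_s.
#' @export
pair_phase_samples <- function(reference_series, paired_series, pair,
                               body_track = NULL) {
  pair <- match.arg(pair, PAIRS)
  cycles <- extract_step_cycles(reference_series, body_track = body_track)
  n_skipped <- 0L
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    ph <- compute_phase(cycles[i, ], paired_series)
    if (is.null(ph)) return(NULL)
    data.frame(
      animal = cycles$animal[i], timepoint = cycles$timepoint[i],
      task = cycles$task[i], surface = cycles$surface[i],
      pass = cycles$pass[i], pair = pair,
      raw_phase = ph$raw_phase, folded_phase = ph$folded_phase,
      frequency_hz = ph$frequency_hz,
      speed_cm_s = cycles$speed_cm_s[i],
      stringsAsFactors = FALSE
    )
  })
  keep <- !vapply(rows, is.null, logical(1))
  n_skipped <- sum(!keep)
  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(animal = character(0), timepoint = character(0),
               task = character(0), surface = character(0),
               pass = character(0), pair = character(0),
               raw_phase = numeric(0), folded_phase = numeric(0),
               frequency_hz = numeric(0), speed_cm_s = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Control variability band for a limb pair
#'
#' Pools folded phases from control timepoints and sets the band
#' mean +/- k * SD (sample SD), clipped to the folded scale [0.5, 1.0].
#' Steps whose folded phase falls outside this band are classified as
#' altered. The default multiplier is k = 2.
#'
#' @param folded numeric vector of folded phases from control timepoints
#'   (>= 2 values).
#' @param k band half-width in SD units.
#' @param pair optional pair label stored with the band.
#' @return object of class \code{control_band}: list with \code{pair},
#'   \code{mean_folded}, \code{sd_folded}, \code{lower}, \code{upper},
#'   \code{k}, \code{n}.
#' @examples
#' build_control_band(c(0.50, 0.55, 0.60))  # mean 0.55, sd 0.05
#' @export
build_control_band <- function(folded, k = 2, pair = NA_character_) {
  if (length(folded) < 2) {
    stop("need at least 2 control samples to build a band")
  }
  if (any(folded < 0.5 - 1e-9 | folded > 1 + 1e-9)) {
    stop("folded phases must lie in [0.5, 1.0]")
  }
  if (k <= 0) stop("k must be positive")
  m <- mean(folded)
  s <- stats::sd(folded)
  structure(
    list(pair = pair, mean_folded = m, sd_folded = s,
         lower = max(0.5, m - k * s), upper = min(1.0, m + k * s),
         k = k, n = length(folded)),
    class = "control_band"
  )
}

#' @export
print.control_band <- function(x, ...) {
  cat(sprintf(
    "Control band%s: mean %.4f, sd %.4f, [%.4f, %.4f] (k = %g, n = %d)\n",
    if (is.na(x$pair)) "" else paste0(" [", x$pair, "]"),
    x$mean_folded, x$sd_folded, x$lower, x$upper, x$k, x$n
  ))
  invisible(x)
}

#' Classify steps as altered against a control band
#'
#' A step is altered when its folded phase lies outside the band's
#' [lower, upper] interval. The pair label of the samples must match the
#' band's (when both carry one).
#'
#' @param samples data.frame of phase samples (needs \code{folded_phase};
#'   a \code{pair} column is checked against the band).
#' @param band \code{control_band}.
#' @return list with \code{samples} (input plus logical \code{altered}),
#'   \code{n_altered}, \code{n_total}.
#' @export
classify_steps <- function(samples, band) {
  stopifnot(inherits(band, "control_band"))
  if (!"folded_phase" %in% names(samples)) {
    stop("samples need a 'folded_phase' column")
  }
  if (!is.na(band$pair) && "pair" %in% names(samples) &&
      nrow(samples) > 0) {
    pr <- unique(samples$pair)
    if (length(pr) != 1 || pr != band$pair) {
      stop("pair mismatch: band is for '", band$pair,
           "' but samples are for '", paste(pr, collapse = ","), "'")
    }
  }
  altered <- samples$folded_phase < band$lower |
    samples$folded_phase > band$upper
  samples$altered <- altered
  list(samples = samples,
       n_altered = sum(altered),
       n_total = length(altered))
}

#' Coefficient of variation of folded phases
#'
#' 100 * sample SD / mean. On the folded scale the mean is at least 0.5,
#' so the statistic is always defined.
#'
#' @param x numeric vector (>= 2 values).
#' @return CoV in percent.
#' @examples
#' coefficient_of_variation(c(0.5, 0.6, 0.7))  # 16.67
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  100 * stats::sd(x) / mean(x)
}

#' Per-group coefficient of variation
#'
#' Computes \code{\link{coefficient_of_variation}} of the folded phase
#' within each (animal, timepoint-group) cell; groups with fewer than two
#' samples are skipped.
#'
#' @param samples phase-sample data.frame with \code{animal} and
#'   \code{folded_phase} columns.
#' @param group additional grouping column name(s), default
#'   \code{"timepoint"}.
#' @return data.frame with the grouping columns, \code{n} and
#'   \code{cov_pct}.
#' @export
cov_by_group <- function(samples, group = "timepoint") {
  cols <- c("animal", group)
  key <- interaction(samples[cols], drop = TRUE)
  rows <- lapply(split(samples, key), function(g) {
    if (nrow(g) < 2) return(NULL)
    cbind(g[1, cols, drop = FALSE],
          data.frame(n = nrow(g),
                     cov_pct = coefficient_of_variation(g$folded_phase)))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Quadrupedal stepping index
#'
#' 100 times the ratio of hindlimb to forelimb step counts over the
#' analysed passes; 100 means strict 1:1 quadrupedal stepping.
#'
#' @param fore_cycles forelimb step count (> 0).
#' @param hind_cycles hindlimb step count.
#' @return index (dimensionless, x 100).
#' @examples
#' stepping_index(10, 10)  # 100
#' @export
stepping_index <- function(fore_cycles, hind_cycles) {
  if (fore_cycles <= 0) {
    stop("stepping index undefined: zero forelimb cycles")
  }
  100 * hind_cycles / fore_cycles
}
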