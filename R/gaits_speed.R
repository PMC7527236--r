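#' Default gait classification bands on the folded phase scale
#'
#' Band edges used by \code{\link{classify_gait}}. The folded scale has
#' three canonical coupling patterns: alternation at 0.5, the
#' phase-shifted (gallop) pattern at 0.75, and synchrony at 1.0. The
#' default bands centre on those values with equal guard bands:
#' alternation [0.5, 0.65), phase-shifted [0.65, 0.85), synchronous
#' [0.85, 1.0].
#'
#' @param alternation_max upper edge of the alternation band.
#' @param sync_min lower edge of the synchronous band.
#' @return named list with the two edges.
#' @export
gait_bands <- function(alternation_max = 0.65, sync_min = 0.85) {
  if (!(0.5 < alternation_max && alternation_max < sync_min &&
        sync_min <= 1)) {
    stop("require 0.5 < alternation_max < sync_min <= 1")
  }
  list(alternation_max = alternation_max, sync_min = sync_min)
}

#' Classify a quadrupedal stride set into a gait
#'
#' Speed-dependent gaits are defined by the left-right coupling at each
#' girdle (folded phases): walk-trot when both girdles alternate; gallop
#' when either girdle shows the intermediate phase-shifted pattern while
#' the hindlimbs are not synchronous; half-bound when the hindlimbs are
#' synchronous and the forelimbs are not; full-bound when both girdles
#' are synchronous. Walk and trot are not distinguished. Combinations
#' outside these definitions (e.g. alternating hindlimbs with synchronous
#' forelimbs) are "unclassified".
#'
#' @param lr_hind_folded,lr_fore_folded folded left-right phases in
#'   [0.5, 1.0] (vectorised, equal length).
#' @param bands band edges from \code{\link{gait_bands}}.
#' @return character vector of gait labels: "walk_trot", "gallop",
#'   "half_bound", "full_bound" or "unclassified".
#' @examples
#' classify_gait(0.5, 0.5)    # walk_trot
#' classify_gait(0.75, 0.75)  # gallop
#' classify_gait(1.0, 0.6)    # half_bound
#' @export
classify_gait <- function(lr_hind_folded, lr_fore_folded,
                          bands = gait_bands()) {
  h <- lr_hind_folded
  f <- lr_fore_folded
  if (length(h) != length(f)) stop("phase vectors differ in length")
  if (any(h < 0.5 | h > 1 | f < 0.5 | f > 1, na.rm = TRUE)) {
    stop("folded phases must lie in [0.5, 1.0]")
  }
  zone <- function(x) {
    ifelse(x < bands$alternation_max, "alt",
           ifelse(x < bands$sync_min, "mid", "sync"))
  }
  hz <- zone(h)
  fz <- zone(f)
  out <- rep("unclassified", length(h))
  out[hz == "alt" & fz == "alt"] <- "walk_trot"
  out[hz == "sync" & fz == "sync"] <- "full_bound"
  out[hz == "sync" & fz != "sync"] <- "half_bound"
  out[hz != "sync" & (hz == "mid" | fz == "mid")] <- "gallop"
  out[is.na(h) | is.na(f)] <- NA_character_
  out
}

#' Phase-frequency tabulation against a step-frequency threshold
#'
#' Counts, per limb pair (and per any further grouping columns present),
#' the steps at or below a step-frequency threshold. The 5 Hz default
#' marks the transition zone from walk-trot to gallop. Samples lacking a
#' frequency are excluded and counted in the \code{n_excluded} attribute.
#' The per-step (phase, frequency) values are returned for polar
#' plotting.
#'
#' @param samples phase-sample data.frame with \code{pair},
#'   \code{raw_phase} and \code{frequency_hz}; an optional
#'   \code{condition} column refines the grouping.
#' @param threshold_hz step-frequency threshold in Hz (default 5).
#' @return list with \code{counts} (pair [, condition], n_at_or_below,
#'   n_total, pct_at_or_below) and \code{polar} (pair [, condition],
#'   raw_phase, frequency_hz).
#' @export
phase_frequency_table <- function(samples, threshold_hz = 5) {
  if (!all(c("pair", "frequency_hz") %in% names(samples))) {
    stop("samples need 'pair' and 'frequency_hz' columns")
  }
  excl <- is.na(samples$frequency_hz)
  s <- samples[!excl, , drop = FALSE]
  gcols <- intersect(c("pair", "condition"), names(s))
  key <- interaction(s[gcols], drop = TRUE)
  counts <- do.call(rbind, lapply(split(s, key), function(g) {
    below <- sum(g$frequency_hz <= threshold_hz)
    cbind(g[1, gcols, drop = FALSE],
          data.frame(n_at_or_below = below, n_total = nrow(g),
                     pct_at_or_below = round(100 * below / nrow(g), 2)))
  }))
  rownames(counts) <- NULL
  polar_cols <- intersect(c(gcols, "raw_phase", "frequency_hz"), names(s))
  out <- list(counts = counts,
              threshold_hz = threshold_hz,
              polar = s[, polar_cols, drop = FALSE])
  attr(out, "n_excluded") <- sum(excl)
  out
}

#' Speed versus spatiotemporal gait variable
#'
#' Spearman rank correlation (average ranks on ties) and ordinary
#' least-squares fit of a spatiotemporal stride variable against body
#' speed. Stride and stance durations shorten with speed; stride length
#' grows.
#'
#' @param cycles \code{step_cycles} data.frame with \code{speed_cm_s};
#'   cycles without speed are dropped.
#' @param variable one of "stride_time", "stance_time", "swing_time",
#'   "stride_length".
#' @return object of class \code{speed_relation}: list with
#'   \code{variable}, \code{spearman_rs}, \code{spearman_p},
#'   \code{slope}, \code{slope_se}, \code{intercept}, \code{r_squared},
#'   \code{n}.
#' @export
speed_relation <- function(cycles,
                           variable = c("stride_time", "stance_time",
                                        "swing_time", "stride_length")) {
  variable <- match.arg(variable)
  col <- switch(variable,
                stride_time = "stride_duration",
                stance_time = "stance_duration",
                swing_time = "swing_duration",
                stride_length = "stride_length_cm")
  keep <- !is.na(cycles$speed_cm_s) & !is.na(cycles[[col]])
  v <- cycles[[col]][keep]
  sp <- cycles$speed_cm_s[keep]
  if (length(sp) < 3) stop("need at least 3 cycles with speed")
  if (stats::sd(sp) == 0) {
    stop("speed is constant; correlation undefined")
  }
  rs <- stats::cor(sp, v, method = "spearman")
  ct <- suppressWarnings(
    stats::cor.test(sp, v, method = "spearman", exact = FALSE)
  )
  fit <- stats::lm(v ~ sp)
  sm <- summary(fit)
  structure(
    list(variable = variable,
         spearman_rs = rs,
         spearman_p = ct$p.value,
         slope = unname(stats::coef(fit)[2]),
         slope_se = sm$coefficients[2, 2],
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         n = length(sp)),
    class = "speed_relation"
  )
}

#' @export
print.speed_relation <- function(x, ...) {
  cat(sprintf(
    "Speed relation: %s vs speed\n  rs = %.3f (p = %.3g), R2 = %.3f, slope = %.4g +/- %.2g, n = %d\n",
    x$variable, x$spearman_rs, x$spearman_p, x$r_squared,
    x$slope, x$slope_se, x$n
  ))
  invisible(x)
}

#' Compare regression slopes of two speed relations
#'
#' t = (b1 - b2) / sqrt(SE1^2 + SE2^2) with n1 + n2 - 4 degrees of
#' freedom, two-tailed.
#'
#' @param rel1,rel2 \code{speed_relation} objects.
#' @return list with \code{t}, \code{df}, \code{p_value}.
#' @export
compare_slopes <- function(rel1, rel2) {
  stopifnot(inherits(rel1, "speed_relation"),
            inherits(rel2, "speed_relation"))
  se <- sqrt(rel1$slope_se^2 + rel2$slope_se^2)
  if (se == 0) stop("zero pooled standard error; t undefined")
  t <- (rel1$slope - rel2$slope) / se
  df <- rel1$n + rel2$n - 4
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}
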