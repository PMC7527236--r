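#' @importFrom stats approx sd setNames ave pnorm pt qnorm runif rnorm cor
#' @importFrom utils read.csv write.csv
NULL

LIMBS <- c("LF", "RF", "LH", "RH")
TASKS <- c("overground", "treadmill", "exploratory", "swim")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-limb footfall event series
#'
#' One limb's ordered paw contact (touch-down) and lift (toe-off) times
#' within a single locomotor pass. Contacts and lifts must each be
#' strictly increasing and must interleave: every lift falls between the
#' contact that opened its stance phase and the next contact of the same
#' paw. A trailing lift after the final contact is permitted (the pass
#' may end mid-stance).
#'
#' @param animal_id,timepoint,pass_id character identifiers. The
#'   timepoint label (e.g. "baseline", "dox_on_d5") determines whether
#'   the pass contributes to the control pool downstream.
#' @param limb one of "LF", "RF", "LH", "RH".
#' @param contacts,lifts numeric times in seconds.
#' @param task locomotor task label ("overground", "treadmill",
#'   "exploratory", "swim").
#' @param surface stepping-surface label (free text, e.g. "coated").
#' @return object of class \code{limb_event_series}.
#' @export
limb_event_series <- function(animal_id, timepoint, pass_id, limb,
                              contacts, lifts = numeric(0),
                              task = "overground", surface = "default") {
  limb <- match.arg(limb, LIMBS)
  task <- match.arg(task, TASKS)
  x <- structure(
    list(animal_id = as.character(animal_id),
         timepoint = as.character(timepoint),
         pass_id = as.character(pass_id),
         limb = limb,
         contacts = as.numeric(contacts),
         lifts = as.numeric(lifts),
         task = task,
         surface = as.character(surface)),
    class = "limb_event_series"
  )
  validate_limb_event_series(x)
  x
}

validate_limb_event_series <- function(x) {
  id <- sprintf("animal %s, pass %s, limb %s", x$animal_id, x$pass_id, x$limb)
  ct <- x$contacts
  lf <- x$lifts
  if (anyNA(ct) || anyNA(lf)) stop("NA event time in ", id)
  if (length(ct) && any(ct < 0) || length(lf) && any(lf < 0)) {
    stop("negative event time in ", id)
  }
  if (is.unsorted(ct, strictly = TRUE)) {
    stop("contacts not strictly increasing in ", id)
  }
  if (is.unsorted(lf, strictly = TRUE)) {
    stop("lifts not strictly increasing in ", id)
  }
  nl <- length(lf)
  nc <- length(ct)
  if (nl > nc) stop("more lifts than contacts in ", id)
  if (nl > 0 && nc == 0) stop("lift without any contact in ", id)
  # lift j belongs to stance opened by contact j
  for (j in seq_len(nl)) {
    if (lf[j] <= ct[j]) {
      stop("events not interleaved (lift at ", lf[j],
           " precedes its contact) in ", id)
    }
    if (j < nc && lf[j] >= ct[j + 1]) {
      stop("events not interleaved (lift at ", lf[j],
           " after the next contact) in ", id)
    }
  }
  invisible(x)
}

#' @export
print.limb_event_series <- function(x, ...) {
  cat(sprintf(
    "Limb event series: %s %s pass %s [%s, %s/%s]\n  %d contacts, %d lifts over %.2f s\n",
    x$animal_id, x$limb, x$pass_id, x$timepoint, x$task, x$surface,
    length(x$contacts), length(x$lifts),
    if (length(x$contacts)) diff(range(c(x$contacts, x$lifts))) else 0
  ))
  invisible(x)
}

#' Read a long-format footfall event table
#'
#' Reads a UTF-8 comma-separated file with one row per event and splits
#' it into validated \code{\link{limb_event_series}} objects, one per
#' (animal, timepoint, pass, limb). The default column names are
#' \code{animal}, \code{timepoint}, \code{pass}, \code{limb},
#' \code{event_type} ("contact"/"lift"), \code{time_s}, with optional
#' \code{task} and \code{surface}; \code{schema} remaps them.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the roles above to the
#'   file's column names, e.g. \code{c(animal = "rat_id")}.
#' @return list of \code{limb_event_series}.
#' @export
read_event_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c(animal = "animal", timepoint = "timepoint", pass = "pass",
            limb = "limb", event_type = "event_type", time = "time_s",
            task = "task", surface = "surface")
  if (!is.null(schema)) cols[names(schema)] <- schema
  required <- cols[c("animal", "timepoint", "pass", "limb",
                     "event_type", "time")]
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("event table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  events_to_series(data.frame(
    animal = as.character(df[[cols["animal"]]]),
    timepoint = as.character(df[[cols["timepoint"]]]),
    pass = as.character(df[[cols["pass"]]]),
    limb = as.character(df[[cols["limb"]]]),
    event_type = as.character(df[[cols["event_type"]]]),
    time_s = as.numeric(df[[cols["time"]]]),
    task = if (cols["task"] %in% names(df))
      as.character(df[[cols["task"]]]) else "overground",
    surface = if (cols["surface"] %in% names(df))
      as.character(df[[cols["surface"]]]) else "default",
    stringsAsFactors = FALSE
  ))
}

#' Split a long event data.frame into validated series
#'
#' @param df data.frame with columns \code{animal}, \code{timepoint},
#'   \code{pass}, \code{limb}, \code{event_type}, \code{time_s} and
#'   optionally \code{task}, \code{surface}.
#' @return list of \code{limb_event_series}.
#' @export
events_to_series <- function(df) {
  if (!"task" %in% names(df)) df$task <- "overground"
  if (!"surface" %in% names(df)) df$surface <- "default"
  bad <- setdiff(unique(df$event_type), c("contact", "lift"))
  if (length(bad)) {
    stop("unknown event_type value(s): ", paste(bad, collapse = ", "))
  }
  key <- interaction(df$animal, df$timepoint, df$pass, df$limb, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_s), ]
    limb_event_series(
      animal_id = g$animal[1], timepoint = g$timepoint[1],
      pass_id = g$pass[1], limb = g$limb[1],
      contacts = g$time_s[g$event_type == "contact"],
      lifts = g$time_s[g$event_type == "lift"],
      task = g$task[1], surface = g$surface[1]
    )
  })
}

#' Write limb event series back to a long-format CSV
#'
#' Inverse of \code{\link{read_event_table}} with default column names;
#' a round trip reproduces the series exactly.
#'
#' @param series list of \code{limb_event_series} (or a single one).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_event_table <- function(series, path) {
  if (inherits(series, "limb_event_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(
      animal = s$animal_id, timepoint = s$timepoint, task = s$task,
      surface = s$surface, pass = s$pass_id, limb = s$limb,
      event_type = rep(c("contact", "lift"),
                       c(length(s$contacts), length(s$lifts))),
      time_s = c(s$contacts, s$lifts),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$animal, out$pass, out$limb, out$time_s), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Planar marker track
#'
#' A 2-D coordinate time series for one anatomical marker, sampled at a
#' constant frame rate. Frame 0 is time 0.
#'
#' @param marker marker name (e.g. "groin", "paw_RH", "iliac_crest").
#' @param frame_rate sampling rate in Hz.
#' @param x,y coordinates in cm, one value per frame.
#' @param t0 time of the first frame in seconds (default 0).
#' @return object of class \code{marker_track} with a \code{time}
#'   component.
#' @export
marker_track <- function(marker, frame_rate, x, y, t0 = 0) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("marker coordinates must be finite")
  }
  structure(
    list(marker = as.character(marker), frame_rate = frame_rate,
         time = t0 + (seq_along(x) - 1) / frame_rate,
         x = as.numeric(x), y = as.numeric(y)),
    class = "marker_track"
  )
}

# Interpolate a track at times tt; error if outside the sampled span.
track_at <- function(track, tt, what = c("x", "y")) {
  what <- match.arg(what)
  if (any(tt < track$time[1] - 1e-9) ||
      any(tt > track$time[length(track$time)] + 1e-9)) {
    stop("marker track '", track$marker,
         "' does not span the requested interval")
  }
  stats::approx(track$time, track[[what]], xout = tt, rule = 2)$y
}

#' Read a long-format marker coordinate table
#'
#' @param path CSV with columns \code{animal}, \code{pass},
#'   \code{frame}, \code{marker}, \code{x_cm}, \code{y_cm}.
#' @param frame_rate sampling rate in Hz (applied to every track).
#' @return nested list: tracks by animal, then pass, then marker name.
#' @export
read_marker_table <- function(path, frame_rate) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "pass", "frame", "marker", "x_cm", "y_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("marker table is missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- list()
  for (g in split(df, interaction(df$animal, df$pass, df$marker, drop = TRUE))) {
    g <- g[order(g$frame), ]
    a <- as.character(g$animal[1]); p <- as.character(g$pass[1])
    out[[a]][[p]][[g$marker[1]]] <-
      marker_track(g$marker[1], frame_rate, g$x_cm, g$y_cm,
                   t0 = g$frame[1] / frame_rate)
  }
  out
}

#' Extract complete step cycles from a limb event series
#'
#' A step cycle (stride) runs from one paw contact to the next contact of
#' the same paw. Stance is contact to lift, swing is lift to next
#' contact. The terminal partial cycle (after the last contact) is
#' discarded; only complete strides are analysed. With fewer than two
#' contacts an empty table is returned.
#'
#' When marker tracks are supplied, stride length is the displacement of
#' the limb's paw marker between successive contacts, and speed is the
#' horizontal displacement of the body reference marker over the stride
#' divided by the stride duration.
#'
#' @param series a \code{limb_event_series}.
#' @param body_track optional \code{marker_track} of the body reference
#'   point (e.g. groin) used for speed.
#' @param paw_track optional \code{marker_track} of this limb's paw used
#'   for stride length.
#' @return data.frame of class \code{step_cycles} with columns
#'   \code{animal}, \code{timepoint}, \code{task}, \code{surface},
#'   \code{pass}, \code{limb}, \code{start_contact},
#'   \code{stride_duration}, \code{stance_duration},
#'   \code{swing_duration}, \code{frequency_hz}, \code{stride_length_cm},
#'   \code{speed_cm_s}.
#' @export
extract_step_cycles <- function(series, body_track = NULL, paw_track = NULL) {
  stopifnot(inherits(series, "limb_event_series"))
  ct <- series$contacts
  lf <- series$lifts
  empty <- data.frame(
    animal = character(0), timepoint = character(0), task = character(0),
    surface = character(0), pass = character(0), limb = character(0),
    start_contact = numeric(0), stride_duration = numeric(0),
    stance_duration = numeric(0), swing_duration = numeric(0),
    frequency_hz = numeric(0), stride_length_cm = numeric(0),
    speed_cm_s = numeric(0), stringsAsFactors = FALSE
  )
  class(empty) <- c("step_cycles", "data.frame")
  if (length(ct) < 2) return(empty)

  n <- length(ct) - 1L
  start <- ct[seq_len(n)]
  stride <- diff(ct)
  # the lift inside each stride window (guaranteed by interleaving)
  stance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    in_win <- lf > ct[i] & lf < ct[i + 1]
    if (any(in_win)) stance[i] <- lf[which(in_win)[1]] - ct[i]
  }
  keep <- !is.na(stance)
  out <- data.frame(
    animal = series$animal_id, timepoint = series$timepoint,
    task = series$task, surface = series$surface,
    pass = series$pass_id, limb = series$limb,
    start_contact = start[keep],
    stride_duration = stride[keep],
    stance_duration = stance[keep],
    swing_duration = (stride - stance)[keep],
    frequency_hz = 1 / stride[keep],
    stride_length_cm = NA_real_,
    speed_cm_s = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(paw_track)) {
    x0 <- track_at(paw_track, out$start_contact)
    x1 <- track_at(paw_track, out$start_contact + out$stride_duration)
    y0 <- track_at(paw_track, out$start_contact, "y")
    y1 <- track_at(paw_track, out$start_contact + out$stride_duration, "y")
    out$stride_length_cm <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  }
  if (!is.null(body_track)) {
    out$speed_cm_s <- vapply(seq_len(nrow(out)), function(i) {
      compute_speed(out[i, ], body_track)
    }, numeric(1))
    if (is.null(paw_track)) {
      out$stride_length_cm <- out$speed_cm_s * out$stride_duration
    }
  }
  class(out) <- c("step_cycles", "data.frame")
  out
}

#' Body speed over one stride
#'
#' Horizontal displacement of the body reference marker across the stride
#' interval divided by the stride duration, in cm/s.
#'
#' @param cycle one row of a \code{step_cycles} table (or a list with
#'   \code{start_contact} and \code{stride_duration}).
#' @param body_track \code{marker_track} spanning the stride interval.
#' @return speed in cm/s.
#' @export
compute_speed <- function(cycle, body_track) {
  t0 <- cycle$start_contact
  t1 <- cycle$start_contact + cycle$stride_duration
  (track_at(body_track, t1) - track_at(body_track, t0)) /
    cycle$stride_duration
}
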