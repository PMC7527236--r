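# Interior angle (degrees) at `vertex` between rays vertex->a and
# vertex->b. Points are length-2 numeric vectors or n x 2 matrices.
interior_angle <- function(a, vertex, b) {
  a <- rbind(a); vertex <- rbind(vertex); b <- rbind(b)
  u <- a - vertex
  v <- b - vertex
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  if (any(nu == 0 | nv == 0)) {
    stop("coincident points: angle undefined")
  }
  cosang <- rowSums(u * v) / (nu * nv)
  cosang <- pmin(1, pmax(-1, cosang))  # clamp against rounding
  acos(cosang) * 180 / pi
}

#' Intralimb joint angles over a stride window
#'
#' Three-segment, two-angle hindlimb model: segments iliac crest-hip,
#' hip-ankle and ankle-toe give a proximal angle at the hip (between
#' hip->iliac crest and hip->ankle) and a distal angle at the ankle
#' (between ankle->hip and ankle->toe), evaluated per frame inside the
#' stride window. Frames with coincident points are dropped.
#'
#' @param markers named list of \code{marker_track}s with entries
#'   \code{iliac_crest}, \code{hip}, \code{ankle}, \code{toe}, sampled on
#'   a common clock.
#' @param stride_start,stride_end stride window in seconds.
#' @param stride_id identifier stored with the trace.
#' @return object of class \code{angle_trace}: data.frame with
#'   \code{time}, \code{proximal_deg}, \code{distal_deg}; attributes
#'   \code{stride_id} and \code{n_dropped}.
#' @export
joint_angles <- function(markers, stride_start, stride_end,
                         stride_id = NA_character_) {
  need <- c("iliac_crest", "hip", "ankle", "toe")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    stop("missing marker track(s): ", paste(miss, collapse = ", "))
  }
  tt <- markers$hip$time
  tt <- tt[tt >= stride_start - 1e-9 & tt <= stride_end + 1e-9]
  if (length(tt) == 0) stop("no frames inside the stride window")
  pt <- function(m) cbind(track_at(markers[[m]], tt),
                          track_at(markers[[m]], tt, "y"))
  ic <- pt("iliac_crest"); hp <- pt("hip"); ak <- pt("ankle"); to <- pt("toe")
  prox <- dist <- rep(NA_real_, length(tt))
  ok <- rep(TRUE, length(tt))
  for (i in seq_along(tt)) {
    res <- tryCatch(
      c(interior_angle(ic[i, ], hp[i, ], ak[i, ]),
        interior_angle(hp[i, ], ak[i, ], to[i, ])),
      error = function(e) NULL
    )
    if (is.null(res)) ok[i] <- FALSE else {
      prox[i] <- res[1]; dist[i] <- res[2]
    }
  }
  out <- data.frame(time = tt[ok], proximal_deg = prox[ok],
                    distal_deg = dist[ok])
  class(out) <- c("angle_trace", "data.frame")
  attr(out, "stride_id") <- stride_id
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Range of motion of the proximal and distal angles
#'
#' Peak (max), trough (min) and peak-to-trough excursion per angle over
#' one stride.
#'
#' @param trace \code{angle_trace} with at least 2 frames.
#' @return data.frame with rows "proximal" and "distal" and columns
#'   \code{angle}, \code{peak_deg}, \code{trough_deg},
#'   \code{excursion_deg}.
#' @export
range_of_motion <- function(trace) {
  if (nrow(trace) < 2) stop("need at least 2 frames")
  ang <- c(proximal = "proximal_deg", distal = "distal_deg")
  out <- do.call(rbind, lapply(names(ang), function(a) {
    v <- trace[[ang[[a]]]]
    data.frame(angle = a, peak_deg = max(v), trough_deg = min(v),
               excursion_deg = max(v) - min(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Proximal-distal peak-timing phase
#'
#' Temporal overlap of the peak angular excursions within a stride:
#' the lag from the proximal peak to the distal peak as a fraction of
#' the stride, on the circle [0, 1). 0 denotes in-phase intralimb
#' coordination (coincident peaks). Ties in the maximum take the
#' earliest frame.
#'
#' @param trace \code{angle_trace}.
#' @param stride_duration stride duration in seconds.
#' @return circular value in [0, 1).
#' @export
peak_timing_phase <- function(trace, stride_duration) {
  if (nrow(trace) < 2) stop("need at least 2 frames")
  flat <- function(v) max(v) - min(v) < 1e-12
  if (flat(trace$proximal_deg) || flat(trace$distal_deg)) {
    stop("flat angle trace: peak undefined")
  }
  tp <- trace$time[which.max(trace$proximal_deg)]
  td <- trace$time[which.max(trace$distal_deg)]
  ((td - tp) / stride_duration) %% 1
}

#' Hindpaw base-of-support rotation angle
#'
#' External rotation of the hindpaw at initial contact relative to the
#' body midline, from a three-point model: the angle at the groin
#' between the caudal extension of the body axis (shoulder midpoint ->
#' groin) and the groin -> paw direction. 0 degrees puts the paw on the
#' midline extension; 90 degrees is perpendicular to the body axis.
#'
#' @param shoulder_mid,groin,paw_at_contact length-2 numeric xy
#'   coordinates (cm).
#' @return angle in degrees, in [0, 180].
#' @export
base_of_support_angle <- function(shoulder_mid, groin, paw_at_contact) {
  axis_ext <- groin + (groin - shoulder_mid)  # caudal extension point
  interior_angle(axis_ext, groin, paw_at_contact)
}

#' Trunk angle relative to the water surface
#'
#' Four-point model for swimming posture: the acute angle between the
#' iliac crest -> hip body line and the water-surface line defined by
#' its left and right extremes. 0 degrees is a body held parallel to
#' the surface.
#'
#' @param surface_left,surface_right,iliac_crest,hip length-2 numeric
#'   xy coordinates (cm).
#' @return acute angle in degrees, in [0, 90].
#' @export
trunk_angle <- function(surface_left, surface_right, iliac_crest, hip) {
  s <- surface_right - surface_left
  b <- hip - iliac_crest
  ns <- sqrt(sum(s^2)); nb <- sqrt(sum(b^2))
  if (ns == 0) stop("degenerate water-surface line")
  if (nb == 0) stop("coincident iliac crest and hip")
  cosang <- abs(sum(s * b)) / (ns * nb)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Mean trunk angle per stroke cycle
#'
#' Evaluates \code{\link{trunk_angle}} per frame over each stroke window
#' and averages within the stroke.
#'
#' @param markers named list of \code{marker_track}s with entries
#'   \code{iliac_crest} and \code{hip}.
#' @param surface_left,surface_right fixed xy coordinates of the water
#'   surface extremes.
#' @param strokes data.frame with \code{start} and \code{end} times (s).
#' @return numeric vector, one mean angle (degrees) per stroke.
#' @export
stroke_trunk_angles <- function(markers, surface_left, surface_right,
                                strokes) {
  vapply(seq_len(nrow(strokes)), function(i) {
    tt <- markers$hip$time
    tt <- tt[tt >= strokes$start[i] - 1e-9 & tt <= strokes$end[i] + 1e-9]
    if (length(tt) == 0) return(NA_real_)
    angs <- vapply(tt, function(t1) {
      trunk_angle(surface_left, surface_right,
                  c(track_at(markers$iliac_crest, t1),
                    track_at(markers$iliac_crest, t1, "y")),
                  c(track_at(markers$hip, t1),
                    track_at(markers$hip, t1, "y")))
    }, numeric(1))
    mean(angs)
  }, numeric(1))
}
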