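#' Detect foot-strike and toe-off events from a vertical GRF trace
#'
#' Threshold-based event detection on a single foot's vertical ground
#' reaction force: a foot strike is called at the first sample at or above
#' `threshold` after the force has stayed below it for at least
#' `min_contact`; the matching toe-off at the first subsequent sample where
#' the force drops below `threshold` and stays there for at least
#' `min_contact`. The debounce suppresses threshold chatter; detected
#' events strictly alternate strike/toe-off. A trace that never reaches the
#' threshold yields an empty event table (not an error); non-uniform
#' sampling is an error.
#'
#' @param grf Data frame with numeric columns `time` (s, strictly
#'   increasing, uniformly sampled) and `fz` (N) for one foot.
#' @param threshold Force threshold defining foot contact, N.
#' @param min_contact Debounce duration, s: the minimum time the force must
#'   stay on one side of the threshold for a crossing to count.
#' @param foot Foot label attached to the events.
#' @return Tibble with columns `time`, `foot`, `kind`
#'   (`"foot_strike"`/`"toe_off"`), ordered in time.
#' @export
detect_foot_contacts <- function(grf, threshold = 50, min_contact = 0.02,
                                 foot = "unknown") {
  if (!all(c("time", "fz") %in% names(grf))) {
    stop("`grf` needs columns `time` and `fz`", call. = FALSE)
  }
  t <- grf$time
  fz <- grf$fz
  if (length(t) < 2) stop("GRF trace too short", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("GRF time must be strictly increasing", call. = FALSE)
  period <- median(dt)
  if (max(abs(dt - period)) > 1e-6 * period) {
    stop("GRF trace is not uniformly sampled", call. = FALSE)
  }
  min_samples <- max(1L, round(min_contact / period))

  above <- fz >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  times <- numeric(0)
  kinds <- character(0)
  # armed after a below-run of at least min_samples (or from trace start)
  armed <- !r$values[1]
  in_contact <- FALSE
  for (k in seq_along(r$values)) {
    long_enough <- r$lengths[k] >= min_samples
    if (r$values[k]) {
      if (armed && !in_contact && long_enough) {
        times <- c(times, t[starts[k]])
        kinds <- c(kinds, "foot_strike")
        in_contact <- TRUE
        armed <- FALSE
      }
    } else {
      if (long_enough || k == length(r$values)) {
        if (in_contact) {
          times <- c(times, t[starts[k]])
          kinds <- c(kinds, "toe_off")
          in_contact <- FALSE
        }
        if (long_enough) armed <- TRUE
      }
    }
  }
  tibble::tibble(time = times, foot = foot, kind = kinds)
}

#' Segment strides from ipsilateral foot-strike events
#'
#' A stride is the interval between two consecutive foot strikes of the
#' same foot. Events must strictly alternate strike/toe-off per foot (the
#' detection contract); fewer than two strikes yield an empty table.
#'
#' @param events Event tibble as returned by [detect_foot_contacts()]
#'   (possibly covering several feet).
#' @param foot Which foot to segment.
#' @return Tibble with columns `foot`, `start_time`, `end_time`, `duration`.
#' @export
segment_strides <- function(events, foot) {
  ev <- events[events$foot == foot, ]
  ev <- ev[order(ev$time), ]
  check_alternation(ev)
  strikes <- ev$time[ev$kind == "foot_strike"]
  if (length(strikes) < 2) {
    return(tibble::tibble(foot = character(), start_time = numeric(),
                          end_time = numeric(), duration = numeric()))
  }
  n <- length(strikes)
  tibble::tibble(
    foot = foot,
    start_time = strikes[-n],
    end_time = strikes[-1],
    duration = diff(strikes)
  )
}

check_alternation <- function(ev) {
  if (nrow(ev) < 2) return(invisible(TRUE))
  k <- ev$kind
  if (any(k[-1] == k[-length(k)])) {
    stop("events do not alternate foot_strike/toe_off", call. = FALSE)
  }
  invisible(TRUE)
}

#' Stride length from a device-marker trajectory
#'
#' Straight-line horizontal-plane (x, y) displacement of the foot-mounted
#' device marker between its positions at two ipsilateral foot strikes.
#' Each event time is mapped to the nearest motion-capture frame; a missing
#' (gap) position at either frame flags the stride as unmeasurable.
#'
#' @param traj Single-marker trajectory tibble with columns `frame`, `x`,
#'   `y` (frames 0-based at `rate` Hz).
#' @param start_time,end_time Foot-strike times bounding the stride, s.
#' @param rate Motion-capture frame rate, Hz.
#' @return Stride length in metres, or `NA_real_` if either bounding
#'   position is missing.
#' @export
stride_length <- function(traj, start_time, end_time, rate = 100) {
  f0 <- round(start_time * rate)
  f1 <- round(end_time * rate)
  i0 <- match(f0, traj$frame)
  i1 <- match(f1, traj$frame)
  if (is.na(i0) || is.na(i1)) {
    stop("trajectory does not cover both foot-strike times", call. = FALSE)
  }
  x0 <- traj$x[i0]; y0 <- traj$y[i0]
  x1 <- traj$x[i1]; y1 <- traj$y[i1]
  if (anyNA(c(x0, y0, x1, y1))) return(NA_real_)
  sqrt((x1 - x0)^2 + (y1 - y0)^2)
}

#' Stride cadence from stride duration
#'
#' Number of strides per minute: `60 / duration`.
#'
#' @param duration Stride duration(s), s; must be positive.
#' @return Cadence in strides per minute.
#' @export
stride_cadence <- function(duration) {
  if (any(duration <= 0)) stop("stride duration must be > 0", call. = FALSE)
  60 / duration
}

#' Compute criterion stride metrics for one foot
#'
#' Combines [segment_strides()], [stride_length()] and [stride_cadence()]:
#' one row per stride with duration, horizontal device-marker displacement
#' and cadence. Strides whose length cannot be measured (trajectory gap at
#' a bounding frame) or is non-positive are dropped and counted.
#'
#' @param events Event tibble for the trial.
#' @param traj Device-marker trajectory tibble for the same foot (`frame`,
#'   `x`, `y`).
#' @param foot Foot to process.
#' @param rate Motion-capture frame rate, Hz.
#' @return Tibble with columns `foot`, `start_time`, `end_time`,
#'   `duration`, `length`, `cadence`; attribute `n_dropped` counts excluded
#'   strides.
#' @export
stride_metrics <- function(events, traj, foot, rate = 100) {
  st <- segment_strides(events, foot)
  if (nrow(st) == 0) {
    out <- tibble::tibble(foot = character(), start_time = numeric(),
                          end_time = numeric(), duration = numeric(),
                          length = numeric(), cadence = numeric())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  st$length <- vapply(
    seq_len(nrow(st)),
    function(i) stride_length(traj, st$start_time[i], st$end_time[i], rate),
    numeric(1)
  )
  st$cadence <- stride_cadence(st$duration)
  keep <- !is.na(st$length) & st$length > 0
  out <- st[keep, c("foot", "start_time", "end_time", "duration", "length", "cadence")]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Entry and exit of the measured zone from toe-marker trajectories
#'
#' Zone entry is the first frame at which the leading (most forward) toe
#' marker reaches the zone start; zone exit is the first frame at which the
#' trailing (least forward) toe marker reaches the zone end. An error is
#' raised if the zone is never fully traversed.
#'
#' @param toe_trajs Tibble of toe-marker positions with columns `frame`,
#'   `marker`, `x` (one or two toe markers).
#' @param zone_start,zone_end Forward coordinates of the zone bounds, m.
#' @return List with `entry_frame`, `exit_frame` (0-based frame indices).
#' @export
zone_crossings <- function(toe_trajs, zone_start, zone_end) {
  if (zone_end <= zone_start) stop("zone_end must exceed zone_start", call. = FALSE)
  frames <- sort(unique(toe_trajs$frame))
  wide <- split(toe_trajs$x, toe_trajs$marker)
  xs <- do.call(cbind, wide)
  lead <- apply(xs, 1, max)
  trail <- apply(xs, 1, min)
  if (lead[1] >= zone_end) stop("trajectories start beyond the zone", call. = FALSE)
  entry <- which(lead >= zone_start)[1]
  exit <- which(trail >= zone_end)[1]
  if (is.na(entry) || is.na(exit)) {
    stop("zone never fully traversed", call. = FALSE)
  }
  list(entry_frame = frames[entry], exit_frame = frames[exit])
}
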