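#' Resultant magnitude of a 3-axis kinematic signal
#'
#' Elementwise Euclidean norm `sqrt(vx^2 + vy^2 + vz^2)` of three component
#' series sharing an identical time base, capturing motion occurring
#' forward, laterally and vertically in a single magnitude.
#'
#' @param vx,vy,vz [kin_series()] components on the same time base.
#' @return A [kin_series()] of the resultant magnitude.
#' @export
resultant_magnitude <- function(vx, vy, vz) {
  stop_if_not_series(vx, "vx"); stop_if_not_series(vy, "vy"); stop_if_not_series(vz, "vz")
  if (!isTRUE(all.equal(vx$time, vy$time)) || !isTRUE(all.equal(vx$time, vz$time))) {
    stop("component series must share an identical time base", call. = FALSE)
  }
  kin_series(vx$time, sqrt(vx$value^2 + vy$value^2 + vz$value^2),
             label = "resultant")
}

#' Central-difference differentiation
#'
#' Numerical time derivative using the central difference
#' `a_i = (v_{i+1} - v_{i-1}) / (2 dt)` at interior points. Endpoints use
#' first-order one-sided differences so the output keeps the input's length
#' and time base (which downstream synchronization relies on). Exact for
#' polynomials up to degree two at interior points.
#'
#' @param s A [kin_series()] with at least 3 samples.
#' @return A [kin_series()] of the derivative on the same time base.
#' @export
central_difference <- function(s) {
  stop_if_not_series(s)
  v <- s$value
  n <- length(v)
  if (n < 3) stop("central difference needs at least 3 samples", call. = FALSE)
  dt <- 1 / s$rate
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  kin_series(s$time, d, label = paste0("d/dt ", s$label %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward (zero-phase) application of a low-pass Butterworth
#' design. The requested `order` is the *effective* order of the cascade: a
#' half-order filter is designed and applied twice, and its design cutoff
#' is raised by the standard double-pass correction factor
#' `(sqrt(2) - 1)^(-1/order)` so the -3 dB point of the cascade sits at the
#' nominal `cutoff`. The input is extended by odd reflection at both ends
#' before filtering to suppress edge transients, so DC gain is exactly 1 and
#' phase distortion is zero.
#'
#' @param s A [kin_series()].
#' @param cutoff Nominal -3 dB cutoff frequency, Hz; must be below the
#'   Nyquist frequency.
#' @param order Effective filter order (even).
#' @return The filtered [kin_series()].
#' @export
butterworth_lowpass <- function(s, cutoff, order = 4) {
  stop_if_not_series(s)
  nyq <- s$rate / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency", call. = FALSE)
  }
  if (order %% 2 != 0) stop("`order` must be even", call. = FALSE)
  n_design <- order / 2
  corr <- (sqrt(2) - 1)^(-1 / order)
  wc <- min(cutoff * corr / nyq, 0.999)
  bf <- signal::butter(n_design, wc, type = "low")

  # filter the mean-removed signal: the DC component passes through
  # untouched regardless of coefficient rounding in the design
  m <- mean(s$value)
  x <- s$value - m
  n <- length(x)
  pad <- min(n - 1L, max(12L, 3L * ceiling(s$rate / cutoff)))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]),
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  yp <- signal::filtfilt(bf, xp)
  kin_series(s$time, yp[(pad + 1):(pad + n)] + m, label = s$label)
}

#' Residual-analysis selection of a low-pass cutoff frequency
#'
#' Winter-style residual analysis: for each candidate cutoff in
#' `[fc_min, fc_max]` the RMS residual between the raw signal and its
#' zero-phase Butterworth-filtered version is computed. A straight line is
#' fitted to the residual curve over the noise-dominated upper region of
#' the candidate range and extrapolated to 0 Hz to estimate the noise
#' floor; the chosen cutoff is the smallest candidate whose residual does
#' not exceed that intercept. A degenerate (effectively noise- and
#' signal-free) input selects `fc_min`.
#'
#' @param s A [kin_series()]; its rate must exceed `2 * fc_max`.
#' @param fc_min,fc_max Candidate cutoff range, Hz.
#' @param n_candidates Number of equally spaced candidate cutoffs.
#' @param fit_region Fractions of `fc_max` bounding the noise-dominated
#'   region used for the line fit.
#' @param order Effective filter order passed to [butterworth_lowpass()].
#' @return A list of class `residual_curve`: `candidate_cutoffs`,
#'   `residual_rms`, `chosen_cutoff`, `noise_intercept`.
#' @export
residual_analysis <- function(s, fc_min = 4, fc_max = 20, n_candidates = 33,
                              fit_region = c(0.75, 1), order = 4) {
  stop_if_not_series(s)
  if (s$rate <= 2 * fc_max) {
    stop("sampling rate must exceed 2 * fc_max", call. = FALSE)
  }
  if (fc_min >= fc_max) stop("fc_min must be below fc_max", call. = FALSE)
  fc <- seq(fc_min, fc_max, length.out = n_candidates)
  res <- vapply(fc, function(f) {
    sqrt(mean((s$value - butterworth_lowpass(s, f, order = order)$value)^2))
  }, numeric(1))

  in_fit <- fc >= fit_region[1] * fc_max & fc <= fit_region[2] * fc_max
  if (sum(in_fit) < 2) stop("fit region contains fewer than 2 candidates", call. = FALSE)
  if (all(res < 1e-12)) {
    chosen <- fc_min
    intercept <- 0
  } else {
    fit <- lm(res[in_fit] ~ fc[in_fit])
    intercept <- unname(coef(fit)[1])
    ok <- which(res <= intercept)
    chosen <- if (length(ok) == 0) fc_max else fc[ok[1]]
    chosen <- min(max(chosen, fc_min), fc_max)
  }
  structure(
    list(candidate_cutoffs = fc, residual_rms = res,
         chosen_cutoff = chosen, noise_intercept = intercept),
    class = "residual_curve"
  )
}

#' @export
print.residual_curve <- function(x, ...) {
  cat(sprintf(
    "<residual_curve: %d candidates in [%g, %g] Hz, chosen %.3g Hz, noise intercept %.4g>\n",
    length(x$candidate_cutoffs), min(x$candidate_cutoffs),
    max(x$candidate_cutoffs), x$chosen_cutoff, x$noise_intercept
  ))
  invisible(x)
}

#' Fill short gaps in a marker trajectory
#'
#' Fills runs of missing samples of at most `max_gap_frames` frames by
#' local quintic polynomial interpolation through the (up to) six nearest
#' valid frames on each side. Quintic interpolation reproduces polynomial
#' trajectories up to degree five exactly. Gaps longer than the maximum, or
#' touching a trajectory boundary, are left missing and reported in the
#' `gaps` attribute.
#'
#' @param traj Trajectory tibble with column `frame` and one or more
#'   numeric coordinate columns (e.g. `x`, `y`, `z`) containing `NA` runs.
#' @param max_gap_frames Longest gap (in frames) that will be filled.
#' @return `traj` with fillable gaps interpolated; attribute `gaps` is a
#'   tibble of all gaps with a logical `filled` column.
#' @export
fill_gaps <- function(traj, max_gap_frames = 5) {
  coord_cols <- setdiff(names(traj), c("frame", "marker"))
  coord_cols <- coord_cols[vapply(traj[coord_cols], is.numeric, logical(1))]
  miss <- Reduce(`|`, lapply(traj[coord_cols], is.na))
  gap_log <- list()
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      at_boundary <- i0 == 1 || i1 == nrow(traj)
      fillable <- !at_boundary && (i1 - i0 + 1L) <= max_gap_frames
      if (fillable) {
        left <- max(1L, i0 - 6L):(i0 - 1L)
        right <- (i1 + 1L):min(nrow(traj), i1 + 6L)
        support <- c(left, right)
        support <- support[!miss[support]]
        deg <- min(5L, length(support) - 1L)
        f0 <- mean(traj$frame[support])
        for (cc in coord_cols) {
          fit <- lm(traj[[cc]][support] ~ poly(traj$frame[support] - f0, deg, raw = TRUE))
          xg <- traj$frame[i0:i1] - f0
          pred <- cbind(1, outer(xg, seq_len(deg), `^`)) %*% coef(fit)
          traj[[cc]][i0:i1] <- as.numeric(pred)
        }
      }
      gap_log[[length(gap_log) + 1]] <- tibble::tibble(
        start_frame = traj$frame[i0], end_frame = traj$frame[i1],
        n_frames = i1 - i0 + 1L, filled = fillable
      )
    }
  }
  attr(traj, "gaps") <- if (length(gap_log)) dplyr::bind_rows(gap_log) else
    tibble::tibble(start_frame = integer(), end_frame = integer(),
                   n_frames = integer(), filled = logical())
  traj
}
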