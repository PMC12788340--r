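#' Sprint kinematics parameters for the synthetic trial generator
#'
#' Defines the ground-truth gait and centre-of-mass (COM) model for one
#' simulated 10 m fly sprint: an approach run followed by a measured 10 m
#' zone. Forward COM velocity follows a mono-exponential rise
#' `v(t) = peak_velocity * (1 - exp(-t / tau))`, with a small vertical COM
#' oscillation at twice the stride frequency (once per step). Defaults are
#' simulator choices representative of trained sprinting adults, not
#' estimates of any particular population.
#'
#' @param peak_velocity Asymptotic sprint velocity, m/s.
#' @param tau Velocity rise time constant, s.
#' @param approach_length Run-up distance before the measured zone, m.
#' @param zone_length Length of the measured fly zone, m.
#' @param stride_frequency Full gait-cycle frequency per foot, Hz.
#' @param duty_factor Fraction of the stride period each foot spends in
#'   stance (0 < duty_factor < 1).
#' @param body_weight Participant body weight, N.
#' @param com_height Mean COM height, m.
#' @param com_vert_amp Amplitude of the vertical COM oscillation, m.
#' @param grf_peak_multiple Peak vertical ground reaction force as a multiple
#'   of body weight.
#' @param swing_height Peak height of the foot-mounted device marker during
#'   swing, m.
#' @param toe_offset Forward offset of the toe marker from the device
#'   marker, m.
#' @param foot_spacing Lateral distance of each foot from the midline, m.
#' @param first_stance Time of the first (left) stance onset, s.
#' @param run_out Distance simulated beyond the zone exit, m.
#' @param seed Integer seed for the kinematics random stream (used by
#'   [generate_cohort()]; [simulate_criterion_trial()] itself is
#'   deterministic).
#'
#' @return A list of class `sprint_params`.
#' @export
sprint_params <- function(peak_velocity = 8.2,
                          tau = 1.2,
                          approach_length = 10,
                          zone_length = 10,
                          stride_frequency = 2.15,
                          duty_factor = 0.24,
                          body_weight = 700,
                          com_height = 1.0,
                          com_vert_amp = 0.025,
                          grf_peak_multiple = 2.2,
                          swing_height = 0.15,
                          toe_offset = 0.18,
                          foot_spacing = 0.12,
                          first_stance = 0.3,
                          run_out = 6.5,
                          seed = 1L) {
  p <- list(
    peak_velocity = peak_velocity, tau = tau,
    approach_length = approach_length, zone_length = zone_length,
    stride_frequency = stride_frequency, duty_factor = duty_factor,
    body_weight = body_weight, com_height = com_height,
    com_vert_amp = com_vert_amp, grf_peak_multiple = grf_peak_multiple,
    swing_height = swing_height, toe_offset = toe_offset,
    foot_spacing = foot_spacing, first_stance = first_stance,
    run_out = run_out, seed = as.integer(seed)
  )
  if (p$peak_velocity <= 0) stop("peak_velocity must be > 0", call. = FALSE)
  if (p$tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (p$duty_factor <= 0 || p$duty_factor >= 1) {
    stop("duty_factor must lie strictly between 0 and 1", call. = FALSE)
  }
  if (p$zone_length <= 0) stop("zone_length must be > 0", call. = FALSE)
  if (p$stride_frequency <= 0) stop("stride_frequency must be > 0", call. = FALSE)
  if (p$body_weight <= 0) stop("body_weight must be > 0", call. = FALSE)
  class(p) <- "sprint_params"
  p
}

#' Device error model for the synthetic IMU emulator
#'
#' Describes how the emulated foot-mounted IMU distorts ground truth:
#' a multiplicative scale and additive bias on velocity, white measurement
#' noise on the 10 Hz velocity and acceleration streams, a constant clock
#' lag between device and criterion, Gaussian jitter on stride-event
#' timestamps, and bias plus noise on reported stride lengths. Defaults give
#' a device that underestimates velocity and stride length and lags the
#' criterion clock; magnitudes are of the order reported for foot-mounted
#' IMU systems during sprinting. The sample-level velocity noise default is
#' small because commercial foot-IMU velocity outputs are already smoothed
#' by the vendor's state estimator.
#'
#' @param velocity_bias Additive velocity bias, m/s (negative = device
#'   underestimates).
#' @param velocity_scale Multiplicative velocity scale (1 = none).
#' @param velocity_noise_sd SD of white noise on 10 Hz velocity samples, m/s.
#' @param accel_noise_sd SD of white noise on 10 Hz acceleration samples,
#'   m/s^2.
#' @param lag Device clock lag relative to the criterion clock, s (may be
#'   negative).
#' @param event_jitter_sd SD of Gaussian jitter on stride-event timestamps, s.
#' @param stride_length_bias Additive bias on reported stride lengths, m.
#' @param stride_length_noise_sd SD of noise on reported stride lengths, m.
#' @param seed Integer seed for the sensor-noise random stream, independent
#'   of the kinematics stream.
#'
#' @return A list of class `device_error_model`.
#' @export
device_error_model <- function(velocity_bias = -0.5,
                               velocity_scale = 1,
                               velocity_noise_sd = 0.05,
                               accel_noise_sd = 0.3,
                               lag = 0.3,
                               event_jitter_sd = 0.005,
                               stride_length_bias = -0.07,
                               stride_length_noise_sd = 0.15,
                               seed = 20L) {
  em <- list(
    velocity_bias = velocity_bias, velocity_scale = velocity_scale,
    velocity_noise_sd = velocity_noise_sd, accel_noise_sd = accel_noise_sd,
    lag = lag, event_jitter_sd = event_jitter_sd,
    stride_length_bias = stride_length_bias,
    stride_length_noise_sd = stride_length_noise_sd, seed = as.integer(seed)
  )
  sds <- c(em$velocity_noise_sd, em$accel_noise_sd, em$event_jitter_sd,
           em$stride_length_noise_sd)
  if (any(sds < 0)) stop("noise sd fields must be >= 0", call. = FALSE)
  class(em) <- "device_error_model"
  em
}

#' Identity (error-free) device model
#'
#' Convenience constructor: the device reproduces ground truth exactly.
#' @param seed Seed for the (unused) noise stream.
#' @return A `device_error_model` with all biases, scales-from-unity, noise
#'   terms and the lag set to zero.
#' @export
identity_error_model <- function(seed = 20L) {
  device_error_model(
    velocity_bias = 0, velocity_scale = 1, velocity_noise_sd = 0,
    accel_noise_sd = 0, lag = 0, event_jitter_sd = 0,
    stride_length_bias = 0, stride_length_noise_sd = 0, seed = seed
  )
}

## --- ground-truth closed-form kinematics -------------------------------

com_forward_position <- function(p, t) {
  t <- pmax(t, 0)
  p$peak_velocity * (t + p$tau * (exp(-t / p$tau) - 1))
}

com_forward_velocity <- function(p, t) {
  ifelse(t < 0, 0, p$peak_velocity * (1 - exp(-pmax(t, 0) / p$tau)))
}

com_vertical_position <- function(p, t) {
  w <- 2 * pi * 2 * p$stride_frequency
  p$com_height + p$com_vert_amp * cos(w * pmax(t, 0))
}

com_vertical_velocity <- function(p, t) {
  w <- 2 * pi * 2 * p$stride_frequency
  ifelse(t < 0, 0, -p$com_vert_amp * w * sin(w * pmax(t, 0)))
}

#' Ground-truth resultant COM velocity and acceleration
#'
#' Closed-form truth used by the device emulator and by parameter-recovery
#' experiments: the magnitude of the (forward, vertical) COM velocity vector
#' and its exact time derivative. Lateral COM motion is zero in this model.
#'
#' @param p A [sprint_params()] object.
#' @param t Numeric vector of times, s. Times before the sprint start map to
#'   zero velocity.
#' @return Numeric vector, m/s (velocity) or m/s^2 (acceleration).
#' @export
true_resultant_velocity <- function(p, t) {
  vx <- com_forward_velocity(p, t)
  vz <- com_vertical_velocity(p, t)
  sqrt(vx^2 + vz^2)
}

#' @rdname true_resultant_velocity
#' @export
true_resultant_acceleration <- function(p, t) {
  w <- 2 * pi * 2 * p$stride_frequency
  vx <- com_forward_velocity(p, t)
  vz <- com_vertical_velocity(p, t)
  ax <- ifelse(t < 0, 0, p$peak_velocity / p$tau * exp(-pmax(t, 0) / p$tau))
  az <- ifelse(t < 0, 0, -p$com_vert_amp * w^2 * cos(w * pmax(t, 0)))
  v <- sqrt(vx^2 + vz^2)
  out <- ifelse(v > 1e-12, (vx * ax + vz * az) / pmax(v, 1e-12), sqrt(ax^2 + az^2))
  out
}

## --- stride schedule and foot trajectories -----------------------------

# Stance onsets per foot: constant stride period, feet offset by half a
# period; per-foot stance duration = duty_factor * stride period.
stride_schedule <- function(p, t_end) {
  period <- 1 / p$stride_frequency
  stance <- p$duty_factor * period
  if (stance >= period) {
    stop("stance windows overlap on the same foot (duty_factor too large)",
         call. = FALSE)
  }
  onsets <- function(t0) {
    o <- seq(t0, t_end - stance, by = period)
    o[o >= 0]
  }
  list(
    period = period, stance = stance,
    left = onsets(p$first_stance),
    right = onsets(p$first_stance + period / 2)
  )
}

# Device-marker forward positions at each stance: foot planted under the COM
# at mid-stance.
stance_positions <- function(p, onsets, stance) {
  com_forward_position(p, onsets + stance / 2)
}

# Piecewise foot trajectory: stationary at the planted position during
# stance, cosine-eased forward translation plus a sine vertical arc during
# swing.
foot_trajectory <- function(t, onsets, positions, stance, ground_z, swing_height) {
  n <- length(onsets)
  x <- numeric(length(t))
  z <- rep(ground_z, length(t))
  idx <- findInterval(t, onsets)
  pre <- idx == 0
  x[pre] <- positions[1]
  for (k in seq_len(n)) {
    sel <- idx == k
    if (!any(sel)) next
    tk <- t[sel]
    in_stance <- tk <= onsets[k] + stance
    xk <- numeric(length(tk))
    zk <- rep(ground_z, length(tk))
    xk[in_stance] <- positions[k]
    if (k < n) {
      sw <- !in_stance
      u <- (tk[sw] - onsets[k] - stance) / (onsets[k + 1] - onsets[k] - stance)
      u <- pmin(pmax(u, 0), 1)
      xk[sw] <- positions[k] + (positions[k + 1] - positions[k]) * (1 - cos(pi * u)) / 2
      zk[sw] <- ground_z + swing_height * sin(pi * u)
    } else {
      xk[!in_stance] <- positions[k]
    }
    x[sel] <- xk
    z[sel] <- zk
  }
  list(x = x, z = z)
}

# Vertical GRF for one foot: a half-sine bump per stance with a sharpened
# (square-root) rise so the force crosses a 50 N detection threshold within
# a fraction of a millisecond of true stance onset, mimicking the steep
# loading rates of sprint impacts. Exactly zero outside stance.
grf_trace <- function(t, onsets, stance, peak) {
  fz <- numeric(length(t))
  for (o in onsets) {
    sel <- t > o & t < o + stance
    if (!any(sel)) next
    phase <- (t[sel] - o) / stance
    fz[sel] <- fz[sel] + peak * sqrt(sin(pi * phase))
  }
  fz
}

#' Simulate the criterion (motion capture + force plate) side of a trial
#'
#' Generates marker trajectories at 100 Hz and per-foot vertical ground
#' reaction force (GRF) traces at 1000 Hz for one 10 m fly sprint with known
#' ground truth. Markers comprise a COM marker, per-foot toe markers and
#' per-foot device markers (the reflective markers attached to the IMUs).
#' The device marker is stationary during each stance and translates forward
#' during swing; each stance produces a GRF bump that peaks above body
#' weight and is exactly zero outside the stance window. Exact stance
#' onset/offset times are recorded in `true_events`, and per-stride
#' ground-truth metrics in `true_strides`. The function is deterministic.
#'
#' @param params A [sprint_params()] object.
#' @param trial_id,participant_id Identifiers attached to the trial.
#' @param mocap_rate Marker sampling rate, Hz.
#' @param grf_rate Force-plate sampling rate, Hz.
#'
#' @return An object of class `criterion_trial`: a list with elements
#'   `markers` (tibble: frame, marker, x, y, z), `grf` (tibble: time, foot,
#'   fz), `zone_start`, `zone_end`, `true_events`, `true_strides`, `params`
#'   and the two sampling rates.
#' @export
simulate_criterion_trial <- function(params,
                                     trial_id = 1L,
                                     participant_id = 1L,
                                     mocap_rate = 100,
                                     grf_rate = 1000) {
  p <- params
  if (!inherits(p, "sprint_params")) stop("`params` must be a sprint_params object", call. = FALSE)
  zone_start <- p$approach_length
  zone_end <- p$approach_length + p$zone_length

  # simulate until the COM has passed the zone exit by `run_out` metres
  target <- zone_end + p$run_out
  t_end <- stats::uniroot(
    function(t) com_forward_position(p, t) - target,
    lower = 1e-6, upper = 400 / p$peak_velocity + 10 * p$tau
  )$root
  t_end <- ceiling(t_end * mocap_rate) / mocap_rate

  sched <- stride_schedule(p, t_end)
  pos_l <- stance_positions(p, sched$left, sched$stance)
  pos_r <- stance_positions(p, sched$right, sched$stance)

  frames <- 0:(t_end * mocap_rate)
  tm <- frames / mocap_rate

  com <- tibble::tibble(
    frame = frames, marker = "com",
    x = com_forward_position(p, tm), y = 0,
    z = com_vertical_position(p, tm)
  )
  traj_l <- foot_trajectory(tm, sched$left, pos_l, sched$stance, 0.05, p$swing_height)
  traj_r <- foot_trajectory(tm, sched$right, pos_r, sched$stance, 0.05, p$swing_height)
  dev_l <- tibble::tibble(frame = frames, marker = "left_device",
                          x = traj_l$x, y = p$foot_spacing, z = traj_l$z)
  dev_r <- tibble::tibble(frame = frames, marker = "right_device",
                          x = traj_r$x, y = -p$foot_spacing, z = traj_r$z)
  toe_l <- tibble::tibble(frame = frames, marker = "left_toe",
                          x = traj_l$x + p$toe_offset, y = p$foot_spacing,
                          z = 0.02 + 0.8 * (traj_l$z - 0.05))
  toe_r <- tibble::tibble(frame = frames, marker = "right_toe",
                          x = traj_r$x + p$toe_offset, y = -p$foot_spacing,
                          z = 0.02 + 0.8 * (traj_r$z - 0.05))
  markers <- dplyr::bind_rows(com, dev_l, dev_r, toe_l, toe_r)

  tg <- seq(0, t_end, by = 1 / grf_rate)
  peak <- p$grf_peak_multiple * p$body_weight
  grf <- dplyr::bind_rows(
    tibble::tibble(time = tg, foot = "left",
                   fz = grf_trace(tg, sched$left, sched$stance, peak)),
    tibble::tibble(time = tg, foot = "right",
                   fz = grf_trace(tg, sched$right, sched$stance, peak))
  )

  events <- dplyr::bind_rows(
    tibble::tibble(time = sched$left, foot = "left", kind = "foot_strike"),
    tibble::tibble(time = sched$left + sched$stance, foot = "left", kind = "toe_off"),
    tibble::tibble(time = sched$right, foot = "right", kind = "foot_strike"),
    tibble::tibble(time = sched$right + sched$stance, foot = "right", kind = "toe_off")
  )
  events <- dplyr::arrange(events, .data$time, .data$foot)

  true_strides <- dplyr::bind_rows(
    stride_truth("left", sched$left, pos_l, sched$period),
    stride_truth("right", sched$right, pos_r, sched$period)
  )

  structure(
    list(
      trial_id = trial_id, participant_id = participant_id,
      markers = markers, mocap_rate = mocap_rate,
      grf = grf, grf_rate = grf_rate,
      zone_start = zone_start, zone_end = zone_end,
      true_events = events, true_strides = true_strides,
      params = p, t_end = t_end
    ),
    class = "criterion_trial"
  )
}

stride_truth <- function(foot, onsets, positions, period) {
  n <- length(onsets)
  if (n < 2) {
    return(tibble::tibble(foot = character(), start_time = numeric(),
                          end_time = numeric(), duration = numeric(),
                          length = numeric(), cadence = numeric()))
  }
  tibble::tibble(
    foot = foot,
    start_time = onsets[-n],
    end_time = onsets[-1],
    duration = diff(onsets),
    length = abs(diff(positions)),
    cadence = 60 / diff(onsets)
  )
}

#' @export
print.criterion_trial <- function(x, ...) {
  cat(sprintf(
    "<criterion_trial %s/%s: %.2f s, %d markers @ %g Hz, GRF @ %g Hz, zone [%g, %g] m>\n",
    x$participant_id, x$trial_id, x$t_end,
    length(unique(x$markers$marker)), x$mocap_rate, x$grf_rate,
    x$zone_start, x$zone_end
  ))
  invisible(x)
}

#' Degrade a criterion trial into an emulated device export
#'
#' Applies a [device_error_model()] to the ground truth of a simulated
#' trial, producing what the foot-mounted IMU system would export: 10 Hz
#' instantaneous velocity and acceleration series and event-based stride
#' records. Velocity samples are `scale * v_true(t - lag) + bias + noise`;
#' acceleration samples analogously from the true resultant acceleration
#' (scale and noise, no additive bias). Stride records take the true event
#' times shifted by the lag with Gaussian timestamp jitter, and stride
#' lengths with additive bias and noise; durations and cadences are
#' recomputed from the jittered timestamps so the records stay internally
#' consistent. Deterministic given `em$seed`.
#'
#' @param trial A `criterion_trial` from [simulate_criterion_trial()].
#' @param em A [device_error_model()].
#' @param device_rate Output sampling rate of the velocity/acceleration
#'   streams, Hz.
#' @return An object of class `device_trial` with elements `velocity` and
#'   `acceleration` ([kin_series()] at `device_rate`) and `stride_records`
#'   (tibble: time, foot, length, duration, cadence).
#' @export
degrade_to_device <- function(trial, em, device_rate = 10) {
  if (!inherits(trial, "criterion_trial")) stop("`trial` must be a criterion_trial", call. = FALSE)
  if (!inherits(em, "device_error_model")) stop("`em` must be a device_error_model", call. = FALSE)
  p <- trial$params
  td <- seq(0, floor(trial$t_end * device_rate) / device_rate, by = 1 / device_rate)

  out <- withr::with_seed(em$seed %% 2147483647L, {
    v <- em$velocity_scale * true_resultant_velocity(p, td - em$lag) +
      em$velocity_bias + rnorm(length(td), 0, em$velocity_noise_sd)
    a <- em$velocity_scale * true_resultant_acceleration(p, td - em$lag) +
      rnorm(length(td), 0, em$accel_noise_sd)

    recs <- lapply(c("left", "right"), function(ft) {
      ts <- trial$true_strides[trial$true_strides$foot == ft, ]
      if (nrow(ts) == 0) return(NULL)
      strikes <- c(ts$start_time[1], ts$end_time)
      jittered <- strikes + em$lag + rnorm(length(strikes), 0, em$event_jitter_sd)
      dur <- diff(jittered)
      len <- ts$length + em$stride_length_bias +
        rnorm(nrow(ts), 0, em$stride_length_noise_sd)
      tibble::tibble(time = jittered[-1], foot = ft, length = len,
                     duration = dur, cadence = 60 / dur)
    })
    list(v = v, a = a, records = dplyr::bind_rows(recs))
  })

  records <- dplyr::arrange(out$records, .data$time)
  if (any(records$duration <= 0)) {
    stop("error model produced non-positive stride durations", call. = FALSE)
  }
  if (any(records$length <= 0)) {
    stop("error model produced non-positive stride lengths", call. = FALSE)
  }

  structure(
    list(
      trial_id = trial$trial_id, participant_id = trial$participant_id,
      velocity = kin_series(td, out$v, label = "device velocity"),
      acceleration = kin_series(td, out$a, label = "device acceleration"),
      stride_records = records, device_rate = device_rate, em = em
    ),
    class = "device_trial"
  )
}

#' @export
print.device_trial <- function(x, ...) {
  cat(sprintf(
    "<device_trial %s/%s: %d velocity samples @ %g Hz, %d stride records>\n",
    x$participant_id, x$trial_id, length(x$velocity), x$device_rate,
    nrow(x$stride_records)
  ))
  invisible(x)
}

#' Generate a cohort of paired criterion/device trials
#'
#' Draws participant-level kinematic parameters around the supplied
#' `params` (peak velocity, rise constant, stride frequency, duty factor and
#' body weight), adds a small trial-to-trial jitter on peak velocity, and
#' simulates each trial with its emulated device export. Two independent
#' random streams are derived from `seed`: one for kinematics jitter and one
#' family of per-trial sensor-noise seeds, so changing the error model
#' parameters never changes the underlying gait. The error model itself is
#' applied identically to every trial (between-trial error variation is not
#' modelled).
#'
#' @param n_participants Number of participants (>= 1).
#' @param trials_per_participant Trials per participant.
#' @param params Baseline [sprint_params()] around which participants are
#'   jittered.
#' @param em [device_error_model()] applied to every trial.
#' @param seed Integer master seed; the output is fully reproducible from it.
#' @return A list of length `n_participants * trials_per_participant`; each
#'   element is a list with components `criterion` and `device`.
#' @export
generate_cohort <- function(n_participants,
                            trials_per_participant,
                            params = sprint_params(),
                            em = device_error_model(),
                            seed = 1L) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (trials_per_participant < 1) stop("trials_per_participant must be >= 1", call. = FALSE)
  seed <- as.integer(seed)

  draws <- withr::with_seed(seed, {
    pp <- lapply(seq_len(n_participants), function(i) {
      list(
        peak_velocity = max(5, rnorm(1, params$peak_velocity, 0.6)),
        tau = max(0.6, rnorm(1, params$tau, 0.12)),
        stride_frequency = min(2.8, max(1.6, rnorm(1, params$stride_frequency, 0.08))),
        duty_factor = min(0.35, max(0.15, rnorm(1, params$duty_factor, 0.015))),
        body_weight = max(450, rnorm(1, params$body_weight, 80))
      )
    })
    tj <- matrix(rnorm(n_participants * trials_per_participant, 0, 0.12),
                 nrow = n_participants)
    list(participants = pp, trial_jitter = tj)
  })

  pairs <- vector("list", n_participants * trials_per_participant)
  k <- 0
  for (i in seq_len(n_participants)) {
    pi <- draws$participants[[i]]
    for (j in seq_len(trials_per_participant)) {
      k <- k + 1
      p_ij <- params
      p_ij$peak_velocity <- max(5, pi$peak_velocity + draws$trial_jitter[i, j])
      p_ij$tau <- pi$tau
      p_ij$stride_frequency <- pi$stride_frequency
      p_ij$duty_factor <- pi$duty_factor
      p_ij$body_weight <- pi$body_weight
      p_ij$seed <- (seed + 7919L * i + 13L * j) %% 2147483647L
      em_ij <- em
      em_ij$seed <- (seed + 1000003L + 7919L * i + 104729L * j) %% 2147483647L
      crit <- simulate_criterion_trial(p_ij, trial_id = j, participant_id = i)
      pairs[[k]] <- list(criterion = crit, device = degrade_to_device(crit, em_ij))
    }
  }
  pairs
}
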