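#' Configuration for an end-to-end validation run
#'
#' Bundles every tunable of the pipeline: cohort size, the ground-truth
#' sprint model, the device error model, filtering, synchronization and
#' stride-matching settings, the LoA mode(s) to report, output directory
#' and master seed. `cutoff_velocity`/`cutoff_acceleration` of `NULL`
#' select the cutoff per trial by residual analysis; numeric values fix
#' them globally.
#'
#' @param n_participants,trials_per_participant Cohort dimensions.
#' @param params Baseline [sprint_params()].
#' @param em [device_error_model()] applied to every trial.
#' @param filter List: `order`, `cutoff_velocity`, `cutoff_acceleration`.
#' @param residual List: `fc_min`, `fc_max`, `n_candidates`, `fit_region`.
#' @param sync List: `max_lag` (s), `min_overlap` (samples), `center`
#'   (use bias-insensitive mean-centred RMSE in the lag search).
#' @param matching_tolerance Stride-event matching tolerance, s.
#' @param loa_modes LoA modes to report.
#' @param grf_threshold Foot-contact force threshold, N.
#' @param min_contact Event-detection debounce, s.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Master seed for the run.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(n_participants = 23,
                              trials_per_participant = 4,
                              params = sprint_params(),
                              em = device_error_model(),
                              filter = list(order = 4,
                                            cutoff_velocity = NULL,
                                            cutoff_acceleration = NULL),
                              residual = list(fc_min = 4, fc_max = 20,
                                              n_candidates = 17,
                                              fit_region = c(0.75, 1)),
                              sync = list(max_lag = 2, min_overlap = 10,
                                          center = TRUE),
                              matching_tolerance = 0.1,
                              loa_modes = c("first_trial", "pooled"),
                              grf_threshold = 50,
                              min_contact = 0.02,
                              out_dir = NULL,
                              seed = 1L) {
  stopifnot(n_participants >= 1, trials_per_participant >= 1,
            inherits(params, "sprint_params"),
            inherits(em, "device_error_model"),
            matching_tolerance > 0, grf_threshold > 0)
  loa_modes <- match.arg(loa_modes, c("first_trial", "pooled"), several.ok = TRUE)
  structure(
    list(n_participants = n_participants,
         trials_per_participant = trials_per_participant,
         params = params, em = em, filter = filter, residual = residual,
         sync = sync, matching_tolerance = matching_tolerance,
         loa_modes = loa_modes, grf_threshold = grf_threshold,
         min_contact = min_contact, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "validation_config"
  )
}

marker_series <- function(trial, marker) {
  m <- trial$markers[trial$markers$marker == marker, ]
  m[order(m$frame), ]
}

#' Derive the filtered criterion velocity and acceleration for one trial
#'
#' Gap-fills the COM marker trajectory, differentiates each axis by central
#' differences, takes the resultant magnitude, selects (or applies) the
#' velocity cutoff, filters, differentiates again for acceleration and
#' filters that with its own cutoff — the criterion-side processing chain.
#'
#' @param trial A `criterion_trial`.
#' @param config A [validation_config()].
#' @return List: `velocity`, `acceleration` (filtered [kin_series()]),
#'   `cutoff_velocity`, `cutoff_acceleration`.
#' @export
derive_criterion_kinematics <- function(trial, config = validation_config()) {
  com <- marker_series(trial, "com")
  if (anyNA(com[c("x", "y", "z")])) com <- fill_gaps(com)
  tt <- com$frame / trial$mocap_rate
  vx <- central_difference(kin_series(tt, com$x))
  vy <- central_difference(kin_series(tt, com$y))
  vz <- central_difference(kin_series(tt, com$z))
  v_raw <- resultant_magnitude(vx, vy, vz)

  rs <- config$residual
  fc_v <- config$filter$cutoff_velocity
  if (is.null(fc_v)) {
    fc_v <- residual_analysis(v_raw, fc_min = rs$fc_min, fc_max = rs$fc_max,
                              n_candidates = rs$n_candidates,
                              fit_region = rs$fit_region,
                              order = config$filter$order)$chosen_cutoff
  }
  v_filt <- butterworth_lowpass(v_raw, fc_v, order = config$filter$order)

  a_raw <- central_difference(v_filt)
  fc_a <- config$filter$cutoff_acceleration
  if (is.null(fc_a)) {
    fc_a <- residual_analysis(a_raw, fc_min = rs$fc_min, fc_max = rs$fc_max,
                              n_candidates = rs$n_candidates,
                              fit_region = rs$fit_region,
                              order = config$filter$order)$chosen_cutoff
  }
  a_filt <- butterworth_lowpass(a_raw, fc_a, order = config$filter$order)
  list(velocity = v_filt, acceleration = a_filt,
       cutoff_velocity = fc_v, cutoff_acceleration = fc_a)
}

subset_series <- function(s, t_lo, t_hi) {
  keep <- s$time >= t_lo - 1e-9 & s$time <= t_hi + 1e-9
  kin_series(s$time[keep], s$value[keep], label = s$label)
}

series_value_at <- function(s, t) {
  idx <- round((t - s$time[1]) * s$rate) + 1L
  ok <- idx >= 1L & idx <= length(s$value)
  out <- rep(NA_real_, length(t))
  out[ok] <- s$value[idx[ok]]
  out
}

#' Process one paired trial through the full comparison chain
#'
#' Runs the criterion-side derivation, zone-crossing detection, GRF-based
#' gait events and stride metrics, minimum-RMSE alignment of the device
#' velocity stream, and stride-event matching, and extracts the paired
#' values of the six reported variables (stride duration, length and
#' cadence; peak, instantaneous velocity; instantaneous acceleration).
#' Instantaneous variables are paired at the device's native sample times
#' inside the measured zone (after alignment), so each exported device
#' sample enters the comparison once.
#'
#' @param criterion A `criterion_trial`.
#' @param device The matching `device_trial`.
#' @param config A [validation_config()].
#' @return List with elements `pairs` (named list of tibbles of paired
#'   values), `events`, `strides`, `alignment`, `matching`, `zone`,
#'   `cutoffs`.
#' @export
process_trial_pair <- function(criterion, device, config = validation_config()) {
  rate <- criterion$mocap_rate
  kin <- derive_criterion_kinematics(criterion, config)

  toes <- criterion$markers[criterion$markers$marker %in% c("left_toe", "right_toe"),
                            c("frame", "marker", "x")]
  zc <- zone_crossings(toes, criterion$zone_start, criterion$zone_end)
  t_entry <- zc$entry_frame / rate
  t_exit <- zc$exit_frame / rate

  events <- dplyr::bind_rows(lapply(c("left", "right"), function(ft) {
    g <- criterion$grf[criterion$grf$foot == ft, c("time", "fz")]
    detect_foot_contacts(g, threshold = config$grf_threshold,
                         min_contact = config$min_contact, foot = ft)
  }))

  strides <- dplyr::bind_rows(lapply(c("left", "right"), function(ft) {
    traj <- marker_series(criterion, paste0(ft, "_device"))
    stride_metrics(events, traj, ft, rate = rate)
  }))
  strides <- strides[strides$start_time >= t_entry & strides$end_time <= t_exit, ]

  v_zone <- subset_series(kin$velocity, t_entry, t_exit)
  dev_v100 <- upsample(device$velocity, rate)
  # judge candidate lags over (nearly) the whole zone window: short partial
  # overlaps at extreme lags otherwise fit spuriously well
  min_overlap <- max(config$sync$min_overlap,
                     ceiling(0.9 * length(v_zone)))
  alignment <- align_min_rmse(v_zone, dev_v100,
                              max_lag = config$sync$max_lag,
                              min_overlap = min_overlap,
                              center = isTRUE(config$sync$center))
  lag <- alignment$lag

  td_aligned <- device$velocity$time - lag
  in_zone <- td_aligned >= t_entry & td_aligned <= t_exit
  crit_v <- series_value_at(kin$velocity, td_aligned[in_zone])
  crit_a <- series_value_at(kin$acceleration, td_aligned[in_zone])
  ok <- !is.na(crit_v) & !is.na(crit_a)

  pairs <- list(
    instantaneous_velocity = tibble::tibble(
      device = device$velocity$value[in_zone][ok], criterion = crit_v[ok]),
    instantaneous_acceleration = tibble::tibble(
      device = device$acceleration$value[in_zone][ok], criterion = crit_a[ok]),
    peak_velocity = tibble::tibble(
      device = max(device$velocity$value[in_zone]),
      criterion = max(v_zone$value))
  )

  dev_recs <- device$stride_records
  dev_recs$time <- dev_recs$time - lag
  crit_for_match <- tibble::tibble(time = strides$end_time, foot = strides$foot)
  matching <- match_stride_events(dev_recs, crit_for_match,
                                  tolerance = config$matching_tolerance)
  mp <- matching$pairs
  pairs$stride_duration <- tibble::tibble(
    device = dev_recs$duration[mp$device_idx],
    criterion = strides$duration[mp$criterion_idx])
  pairs$stride_length <- tibble::tibble(
    device = dev_recs$length[mp$device_idx],
    criterion = strides$length[mp$criterion_idx])
  pairs$stride_cadence <- tibble::tibble(
    device = dev_recs$cadence[mp$device_idx],
    criterion = strides$cadence[mp$criterion_idx])

  list(pairs = pairs, events = events, strides = strides,
       alignment = alignment, matching = matching,
       zone = list(entry_frame = zc$entry_frame, exit_frame = zc$exit_frame,
                   t_entry = t_entry, t_exit = t_exit),
       cutoffs = list(velocity = kin$cutoff_velocity,
                      acceleration = kin$cutoff_acceleration))
}

variable_units <- c(
  stride_duration = "s", stride_length = "m",
  stride_cadence = "strides/min", peak_velocity = "m/s",
  instantaneous_velocity = "m/s", instantaneous_acceleration = "m/s^2"
)

#' Run the full validation pipeline
#'
#' Simulates a cohort of paired trials, processes every pair
#' ([process_trial_pair()]), pools the paired values of the six reported
#' variables across trials, computes the agreement report in the requested
#' LoA modes, and (when `out_dir` is set) writes per-trial intermediates,
#' the report as CSV and JSON, one Bland-Altman plot per variable, and a
#' manifest with MD5 checksums of every artifact. Deterministic given
#' `config$seed`.
#'
#' @param config A [validation_config()].
#' @return List: `report` (tibble), `samples` (named list of
#'   [paired_sample()]), `alignments`, `cutoffs`, `n_trials`, `manifest`
#'   (tibble or `NULL`), `config`.
#' @export
run_validation <- function(config = validation_config()) {
  cohort <- generate_cohort(config$n_participants,
                            config$trials_per_participant,
                            params = config$params, em = config$em,
                            seed = config$seed)
  acc <- list()
  align_rows <- list()
  stride_rows <- list()
  cutoff_rows <- list()
  for (pair in cohort) {
    trial_tag <- sprintf("participant %s trial %s",
                         pair$criterion$participant_id, pair$criterion$trial_id)
    res <- tryCatch(
      process_trial_pair(pair$criterion, pair$device, config),
      error = function(e) {
        stop(sprintf("pipeline failed at %s: %s", trial_tag, conditionMessage(e)),
             call. = FALSE)
      }
    )
    ids <- tibble::tibble(participant_id = pair$criterion$participant_id,
                          trial_id = pair$criterion$trial_id)
    for (v in names(res$pairs)) {
      df <- res$pairs[[v]]
      if (nrow(df) == 0) next
      acc[[v]][[length(acc[[v]]) + 1L]] <- tibble::tibble(
        participant_id = ids$participant_id, trial_id = ids$trial_id,
        device = df$device, criterion = df$criterion)
    }
    align_rows[[length(align_rows) + 1L]] <- tibble::tibble(
      participant_id = ids$participant_id, trial_id = ids$trial_id,
      lag_s = res$alignment$lag, rmse = res$alignment$rmse_at_lag,
      overlap = res$alignment$overlap_samples)
    if (nrow(res$strides)) {
      stride_rows[[length(stride_rows) + 1L]] <- tibble::tibble(
        participant_id = ids$participant_id, trial_id = ids$trial_id,
        res$strides)
    }
    cutoff_rows[[length(cutoff_rows) + 1L]] <- tibble::tibble(
      participant_id = ids$participant_id, trial_id = ids$trial_id,
      cutoff_velocity = res$cutoffs$velocity,
      cutoff_acceleration = res$cutoffs$acceleration)
  }

  samples <- lapply(names(acc), function(v) {
    df <- dplyr::bind_rows(acc[[v]])
    paired_sample(df$participant_id, df$trial_id, df$device, df$criterion,
                  variable = v, units = unname(variable_units[v]))
  })
  names(samples) <- names(acc)
  order_vars <- intersect(names(variable_units), names(samples))
  samples <- samples[order_vars]

  report <- build_report(samples, loa_modes = config$loa_modes)
  alignments <- dplyr::bind_rows(align_rows)
  strides_all <- dplyr::bind_rows(stride_rows)
  cutoffs <- dplyr::bind_rows(cutoff_rows)

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    wr <- function(df, name) {
      fp <- file.path(config$out_dir, name)
      utils::write.csv(df, fp, row.names = FALSE)
      fp
    }
    paths <- c(paths, wr(report, "agreement_report.csv"))
    jp <- file.path(config$out_dir, "agreement_report.json")
    jsonlite::write_json(report, jp, digits = NA, dataframe = "rows")
    paths <- c(paths, jp)
    paths <- c(paths, wr(alignments, "alignment.csv"))
    paths <- c(paths, wr(strides_all, "criterion_strides.csv"))
    paths <- c(paths, wr(cutoffs, "filter_cutoffs.csv"))
    for (v in names(samples)) {
      fp <- file.path(config$out_dir, paste0("bland_altman_", v, ".png"))
      grDevices::png(fp, width = 900, height = 600)
      print(plot_bland_altman(samples[[v]]))
      grDevices::dev.off()
      paths <- c(paths, fp)
    }
    manifest <- tibble::tibble(
      file = basename(paths),
      md5 = unname(tools::md5sum(paths))
    )
    jsonlite::write_json(
      list(seed = config$seed, n_trials = length(cohort),
           files = manifest),
      file.path(config$out_dir, "manifest.json"),
      digits = NA, dataframe = "rows", auto_unbox = TRUE
    )
  }

  list(report = report, samples = samples, alignments = alignments,
       strides = strides_all, cutoffs = cutoffs,
       n_trials = length(cohort), manifest = manifest, config = config)
}

#' Summarize the packaged cohort fixture
#'
#' Per-sport and total trial/stride counts from the packaged cohort table.
#'
#' @param quiet Suppress printing.
#' @return Invisibly, a list with `by_sport` (tibble) and `totals`.
#' @export
summarize_fixture <- function(quiet = FALSE) {
  fx <- load_cohort_fixture()
  by_sport <- dplyr::summarise(
    dplyr::group_by(fx$participants, .data$sport),
    participants = dplyr::n(),
    trials = sum(.data$trials),
    left_strides = sum(.data$left_strides),
    right_strides = sum(.data$right_strides),
    .groups = "drop"
  )
  if (!quiet) {
    print(by_sport)
    cat(sprintf("Total: %d trials, %d left + %d right = %d strides\n",
                fx$totals$trials, fx$totals$left_strides,
                fx$totals$right_strides, fx$totals$strides))
  }
  invisible(list(by_sport = by_sport, totals = fx$totals))
}
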