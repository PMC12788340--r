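#' Upsample a kinematic series by integer-ratio linear interpolation
#'
#' Linearly interpolates a series onto a finer grid spanning the original
#' time range. The target rate must be an integer multiple of the source
#' rate, so every original sample lies on the new grid and is preserved
#' exactly.
#'
#' @param s A [kin_series()].
#' @param target_rate Target sampling rate, Hz.
#' @return A [kin_series()] at `target_rate`.
#' @export
upsample <- function(s, target_rate = 100) {
  stop_if_not_series(s)
  ratio <- target_rate / s$rate
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop("target_rate must be an integer multiple of the source rate", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  n_out <- (length(s$value) - 1L) * ratio + 1L
  tt <- s$time[1] + (seq_len(n_out) - 1L) / target_rate
  vv <- approx(s$time, s$value, xout = tt)$y
  vv[seq(1L, n_out, by = ratio)] <- s$value   # originals preserved bit-exactly
  kin_series(tt, vv, label = s$label)
}

#' Align two series by exhaustive minimum-RMSE lag search
#'
#' Searches integer-sample lags in `[-max_lag, +max_lag]` for the shift of
#' `target` that minimizes the root mean square error against `reference`
#' over the overlapping window. Both series must share the same sampling
#' rate; they may cover different time spans. Lags whose overlap falls
#' below `min_overlap` samples are excluded from the search; if no lag has
#' sufficient overlap, an error is raised. Ties are broken towards the
#' smallest absolute lag, then towards the negative lag.
#'
#' The returned `lag` is the shift to *subtract* from the target's
#' timestamps to bring it onto the reference clock: if the target is the
#' reference delayed by `k` samples, the recovered lag is `+k` samples.
#'
#' With `center = TRUE` the mean over the overlapping window is removed
#' from both series at each candidate lag before the RMSE is computed.
#' This makes the lag estimate insensitive to a constant between-device
#' offset: aligning a biased stream on a rising velocity ramp by plain
#' RMSE otherwise trades the offset against the slope and lands at a
#' systematically wrong lag.
#'
#' @param reference,target [kin_series()] objects at the same rate.
#' @param max_lag Half-width of the lag search window, s.
#' @param lag_step Search step in samples.
#' @param min_overlap Minimum number of overlapping samples for a lag to be
#'   considered.
#' @param center Remove the overlap-window means before computing the RMSE.
#' @return A list of class `alignment_result`: `lag` (s), `lag_samples`,
#'   `rmse_at_lag`, `overlap_samples`, and the searched `lags`/`rmse`
#'   vectors.
#' @export
align_min_rmse <- function(reference, target, max_lag = 2, lag_step = 1,
                           min_overlap = 10, center = FALSE) {
  stop_if_not_series(reference, "reference")
  stop_if_not_series(target, "target")
  if (abs(reference$rate - target$rate) > 1e-6 * reference$rate) {
    stop("reference and target must share the same sampling rate", call. = FALSE)
  }
  rate <- reference$rate
  K <- as.integer(round(max_lag * rate))
  lags <- as.integer(seq(-K, K, by = lag_step))
  base <- round((reference$time[1] - target$time[1]) * rate)
  nr <- length(reference$value)
  nt <- length(target$value)

  rmse <- rep(NA_real_, length(lags))
  overlap <- integer(length(lags))
  for (m in seq_along(lags)) {
    k <- lags[m]
    off <- base + k
    i_lo <- max(1L, 1L - off)
    i_hi <- min(nr, nt - off)
    if (i_hi - i_lo + 1L < min_overlap) next
    i <- i_lo:i_hi
    d <- reference$value[i] - target$value[i + off]
    if (center) d <- d - mean(d)
    overlap[m] <- length(i)
    rmse[m] <- sqrt(mean(d^2))
  }
  if (all(is.na(rmse))) {
    stop("insufficient overlap between series at every searched lag", call. = FALSE)
  }
  best <- which(!is.na(rmse) & rmse == min(rmse, na.rm = TRUE))
  # tie-break: smallest |lag|, then negative before positive
  ord <- order(abs(lags[best]), lags[best])
  pick <- best[ord[1]]
  structure(
    list(
      lag = lags[pick] / rate,
      lag_samples = lags[pick],
      rmse_at_lag = rmse[pick],
      overlap_samples = overlap[pick],
      lags = lags / rate,
      rmse = rmse
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment: lag %+0.4f s (%+d samples), RMSE %.4g over %d samples>\n",
    x$lag, x$lag_samples, x$rmse_at_lag, x$overlap_samples
  ))
  invisible(x)
}

#' Match device stride events to criterion stride events
#'
#' Greedy nearest-time one-to-one matching of stride events between the two
#' systems: candidate pairs on the same foot within `tolerance` seconds are
#' accepted in order of increasing time offset, each event matching at most
#' once. Device timestamps are expected to be already shifted onto the
#' criterion clock (see [align_min_rmse()]). An empty pairing is allowed.
#'
#' @param device_strides,criterion_strides Tibbles with a numeric `time`
#'   column (stride-completion timestamps) and a `foot` column, time-sorted.
#' @param tolerance Maximum |time offset| for a match, s.
#' @return A list of class `matched_strides`: `pairs` (tibble with matched
#'   row indices `device_idx`/`criterion_idx`, the two times and `offset`),
#'   `n_unmatched_device`, `n_unmatched_criterion`.
#' @export
match_stride_events <- function(device_strides, criterion_strides,
                                tolerance = 0.1) {
  nd <- nrow(device_strides)
  nc <- nrow(criterion_strides)
  cand <- NULL
  if (nd > 0 && nc > 0) {
    grid <- expand.grid(device_idx = seq_len(nd), criterion_idx = seq_len(nc))
    grid$offset <- device_strides$time[grid$device_idx] -
      criterion_strides$time[grid$criterion_idx]
    same_foot <- device_strides$foot[grid$device_idx] ==
      criterion_strides$foot[grid$criterion_idx]
    cand <- grid[same_foot & abs(grid$offset) <= tolerance, ]
    cand <- cand[order(abs(cand$offset)), ]
  }
  used_d <- logical(nd)
  used_c <- logical(nc)
  keep <- integer(0)
  if (!is.null(cand) && nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      di <- cand$device_idx[r]; ci <- cand$criterion_idx[r]
      if (!used_d[di] && !used_c[ci]) {
        used_d[di] <- TRUE
        used_c[ci] <- TRUE
        keep <- c(keep, r)
      }
    }
  }
  pairs <- if (length(keep)) {
    tibble::tibble(
      device_idx = cand$device_idx[keep],
      criterion_idx = cand$criterion_idx[keep],
      device_time = device_strides$time[cand$device_idx[keep]],
      criterion_time = criterion_strides$time[cand$criterion_idx[keep]],
      offset = cand$offset[keep]
    )
  } else {
    tibble::tibble(device_idx = integer(), criterion_idx = integer(),
                   device_time = numeric(), criterion_time = numeric(),
                   offset = numeric())
  }
  structure(
    list(pairs = pairs,
         n_unmatched_device = nd - nrow(pairs),
         n_unmatched_criterion = nc - nrow(pairs)),
    class = "matched_strides"
  )
}

#' @export
print.matched_strides <- function(x, ...) {
  cat(sprintf(
    "<matched_strides: %d pairs, %d device / %d criterion unmatched>\n",
    nrow(x$pairs), x$n_unmatched_device, x$n_unmatched_criterion
  ))
  invisible(x)
}
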