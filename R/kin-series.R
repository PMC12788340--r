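#' Uniformly sampled kinematic time series
#'
#' A lightweight container for a uniformly sampled scalar signal (velocity in
#' m/s, acceleration in m/s^2, ...). Sampling uniformity is enforced at
#' construction: the maximum deviation from the nominal period must be below
#' 1e-6 of the period, and all values must be finite.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced.
#' @param value Numeric vector of sample values, same length as `time`.
#' @param label Optional character label (used in printing and reports).
#'
#' @return An object of class `kin_series`: a list with elements `time`,
#'   `value`, `rate` (Hz) and `label`.
#' @export
#' @examples
#' v <- kin_series(seq(0, 1, by = 0.01), sin(seq(0, 1, by = 0.01)))
#' v$rate
kin_series <- function(time, value, label = NULL) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length", call. = FALSE)
  }
  if (length(time) < 2) stop("a kin_series needs at least 2 samples", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("`time` must be strictly increasing", call. = FALSE)
  period <- median(dt)
  if (max(abs(dt - period)) > 1e-6 * period) {
    stop("non-uniform sampling: max period deviation exceeds 1e-6 of the period",
         call. = FALSE)
  }
  if (any(!is.finite(value))) stop("`value` must be finite", call. = FALSE)
  structure(
    list(time = time, value = value, rate = 1 / period, label = label),
    class = "kin_series"
  )
}

#' @export
print.kin_series <- function(x, ...) {
  cat(sprintf(
    "<kin_series%s: %d samples @ %.6g Hz, t = [%.4g, %.4g]>\n",
    if (is.null(x$label)) "" else paste0(" ", x$label),
    length(x$value), x$rate, x$time[1], x$time[length(x$time)]
  ))
  invisible(x)
}

#' @export
length.kin_series <- function(x) length(x$value)

is_kin_series <- function(x) inherits(x, "kin_series")

stop_if_not_series <- function(x, arg = "s") {
  if (!is_kin_series(x)) stop(sprintf("`%s` must be a kin_series", arg), call. = FALSE)
  invisible(x)
}
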