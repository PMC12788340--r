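#' Read and write the trial CSV dialects
#'
#' Plain-CSV serializers for the containers the pipeline exchanges:
#' criterion marker trajectories (`frame,marker,x,y,z`), per-foot vertical
#' GRF traces (`time,foot,fz`), device velocity/acceleration series
#' (`time,value`) and event-based stride records
#' (`time,foot,length,duration,cadence`). Writers are deterministic: the
#' same object always serializes to byte-identical files.
#'
#' @param trial A `criterion_trial`.
#' @param series A [kin_series()].
#' @param records A stride-record tibble.
#' @param path Output/input file path.
#' @return Writers return `path` invisibly; readers return the
#'   corresponding tibble or [kin_series()].
#' @name trial_io
NULL

write_plain_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
write_marker_csv <- function(trial, path) {
  write_plain_csv(trial$markers[, c("frame", "marker", "x", "y", "z")], path)
}

#' @rdname trial_io
#' @export
write_grf_csv <- function(trial, path) {
  write_plain_csv(trial$grf[, c("time", "foot", "fz")], path)
}

#' @rdname trial_io
#' @export
write_device_series_csv <- function(series, path) {
  stop_if_not_series(series, "series")
  write_plain_csv(data.frame(time = series$time, value = series$value), path)
}

#' @rdname trial_io
#' @export
write_stride_records_csv <- function(records, path) {
  write_plain_csv(records[, c("time", "foot", "length", "duration", "cadence")], path)
}

#' @rdname trial_io
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' @rdname trial_io
#' @export
read_grf_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname trial_io
#' @export
read_device_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kin_series(df$time, df$value)
}

#' @rdname trial_io
#' @export
read_stride_records_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
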