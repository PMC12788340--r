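#' Load the packaged cohort fixture
#'
#' Reads the packaged per-participant table of trial and stride counts for
#' the 23-athlete validation cohort (sport code, trials, left and right
#' strides per participant) and recomputes its totals. The packaged totals
#' row is checked against the recomputed column sums; a mismatch indicates
#' a corrupted fixture and is an error.
#'
#' @param path Path to the fixture CSV; defaults to the copy shipped with
#'   the package.
#' @return A list with elements `participants` (tibble of the 23 rows) and
#'   `totals` (list with `trials`, `left_strides`, `right_strides`,
#'   `strides`).
#' @export
#' @examples
#' fx <- load_cohort_fixture()
#' fx$totals$trials
load_cohort_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_cohort.csv", package = "strideval")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("cohort fixture file not found", call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
  need <- c("participant_id", "sport", "trials", "left_strides", "right_strides")
  if (!identical(names(raw), need)) {
    stop("corrupted cohort fixture: unexpected columns", call. = FALSE)
  }
  is_total <- raw$participant_id == "Total"
  if (sum(is_total) != 1) {
    stop("corrupted cohort fixture: totals row missing or duplicated", call. = FALSE)
  }
  participants <- tibble::as_tibble(raw[!is_total, ])
  participants$participant_id <- as.integer(participants$participant_id)
  counts <- c("trials", "left_strides", "right_strides")
  if (any(participants[counts] < 0)) {
    stop("corrupted cohort fixture: negative counts", call. = FALSE)
  }
  packaged <- raw[is_total, counts]
  sums <- vapply(participants[counts], sum, numeric(1))
  if (!all(sums == unlist(packaged))) {
    stop("corrupted cohort fixture: totals row does not equal column sums",
         call. = FALSE)
  }
  list(
    participants = participants,
    totals = list(
      trials = as.integer(sums[["trials"]]),
      left_strides = as.integer(sums[["left_strides"]]),
      right_strides = as.integer(sums[["right_strides"]]),
      strides = as.integer(sums[["left_strides"]] + sums[["right_strides"]])
    )
  )
}
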