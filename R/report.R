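#' Assemble the agreement report table
#'
#' One row per variable per LoA mode, mirroring the layout of a concurrent-
#' validity results table: per-system mean and SD, MAE, RMSE, mean bias
#' with 95% limits of agreement, and Spearman correlation with its
#' magnitude label.
#'
#' @param samples Named list of [paired_sample()] objects.
#' @param loa_modes Character vector of LoA modes to report
#'   (`"first_trial"`, `"pooled"` or both).
#' @return A tibble with one row per variable and mode.
#' @export
build_report <- function(samples, loa_modes = c("first_trial", "pooled")) {
  if (length(samples) < 1) stop("need at least one paired sample", call. = FALSE)
  rows <- list()
  for (nm in names(samples)) {
    for (mode in loa_modes) {
      rows[[length(rows) + 1]] <- agreement_summary(samples[[nm]], loa_mode = mode)
    }
  }
  dplyr::bind_rows(rows)
}

#' Bland-Altman plot for one paired sample
#'
#' Scatter of paired differences (`device - criterion`) against pair means,
#' coloured by participant, with a dashed mean-difference line and dotted
#' 95% limits of agreement.
#'
#' @param p A [paired_sample()].
#' @param loa_mode LoA mode used for the reference lines.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(p, loa_mode = "pooled") {
  ba <- mean_bias_loa(p, mode = loa_mode)
  df <- tibble::tibble(
    mean = (p$device + p$criterion) / 2,
    diff = p$device - p$criterion,
    participant = factor(p$participant_id)
  )
  units <- attr(p, "units") %||% ""
  unit_suffix <- if (nzchar(units)) paste0(" (", units, ")") else ""
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff,
                                   colour = .data$participant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dotted") +
    ggplot2::labs(
      title = attr(p, "variable") %||% "paired sample",
      x = paste0("Mean of systems", unit_suffix),
      y = paste0("Device - criterion", unit_suffix),
      colour = "Participant"
    ) +
    ggplot2::theme_minimal()
}
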