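#' Construct a paired device/criterion sample
#'
#' A tidy container for paired measurements of one variable: one row per
#' measurement pair with participant and trial identifiers. Differences are
#' always taken as `device - criterion`, so a negative bias means the
#' device underestimates the criterion.
#'
#' @param participant_id,trial_id Identifier vectors (recycled if scalar).
#' @param device,criterion Paired measurements; must be finite.
#' @param variable,units Metadata labels carried into reports.
#' @return A tibble of class `paired_sample` with attributes `variable` and
#'   `units`.
#' @export
paired_sample <- function(participant_id, trial_id, device, criterion,
                          variable = "value", units = "") {
  if (length(device) != length(criterion)) {
    stop("`device` and `criterion` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(device)) || any(!is.finite(criterion))) {
    stop("paired values must be finite", call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = rep_len(participant_id, length(device)),
    trial_id = rep_len(trial_id, length(device)),
    device = as.numeric(device),
    criterion = as.numeric(criterion)
  )
  attr(out, "variable") <- variable
  attr(out, "units") <- units
  class(out) <- c("paired_sample", class(out))
  out
}

pair_diffs <- function(p) p$device - p$criterion

filter_loa_mode <- function(p, mode) {
  mode <- match.arg(mode, c("pooled", "first_trial"))
  if (mode == "pooled") return(p)
  first <- tapply(p$trial_id, p$participant_id, min)
  keep <- p$trial_id == unname(first[as.character(p$participant_id)])
  p[keep, ]
}

#' Mean bias and 95% limits of agreement
#'
#' Bland-Altman absolute agreement: mean of the paired differences
#' (`device - criterion`) with limits of agreement at
#' `bias +/- 1.96 * sd(differences)` (sample SD, multiplier fixed at 1.96
#' with no small-sample correction). In `first_trial` mode only each
#' participant's earliest trial is kept before computing, which removes the
#' dependency of repeated trials from the same individual; `pooled` uses
#' all rows.
#'
#' @param p A [paired_sample()] (or any data frame with `device`,
#'   `criterion`, `participant_id`, `trial_id` columns).
#' @param mode `"pooled"` or `"first_trial"`.
#' @param multiplier LoA multiplier (1.96 for 95% limits).
#' @return List: `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`, `mode`.
#' @export
mean_bias_loa <- function(p, mode = "pooled", multiplier = 1.96) {
  q <- filter_loa_mode(p, mode)
  d <- pair_diffs(q)
  if (length(d) < 2) stop("need at least 2 rows after mode filtering", call. = FALSE)
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - multiplier * s, loa_high = bias + multiplier * s,
       n = length(d), mode = mode)
}

#' Mean absolute error of paired differences
#' @param p A [paired_sample()].
#' @return `mean(|device - criterion|)`.
#' @export
mae <- function(p) {
  d <- pair_diffs(p)
  if (length(d) < 1) stop("empty paired sample", call. = FALSE)
  mean(abs(d))
}

#' Root mean square error of paired differences
#' @param p A [paired_sample()].
#' @return `sqrt(mean((device - criterion)^2))`.
#' @export
rmse <- function(p) {
  d <- pair_diffs(p)
  if (length(d) < 1) stop("empty paired sample", call. = FALSE)
  sqrt(mean(d^2))
}

magnitude_bands <- c(trivial = 0.1, small = 0.3, moderate = 0.5,
                     large = 0.7, `very large` = 0.9, `nearly perfect` = Inf)

#' Spearman correlation with a qualitative magnitude label
#'
#' Spearman rank-order correlation (average ranks for ties) between device
#' and criterion, labelled by absolute magnitude with half-open bands:
#' trivial `[0, 0.1)`, small `[0.1, 0.3)`, moderate `[0.3, 0.5)`, large
#' `[0.5, 0.7)`, very large `[0.7, 0.9)`, nearly perfect `[0.9, 1]`.
#' Zero variance in either margin leaves the coefficient undefined and
#' flags the result.
#'
#' @param p A [paired_sample()] with at least 3 rows.
#' @return List: `rho`, `magnitude`, `flagged`.
#' @export
spearman_with_magnitude <- function(p) {
  if (nrow(p) < 3) stop("need at least 3 rows", call. = FALSE)
  if (sd(p$device) == 0 || sd(p$criterion) == 0) {
    return(list(rho = NA_real_, magnitude = NA_character_, flagged = TRUE))
  }
  rho <- cor(p$device, p$criterion, method = "spearman")
  list(rho = rho, magnitude = magnitude_label(rho), flagged = FALSE)
}

magnitude_label <- function(rho) {
  # round away float fuzz so printed band boundaries behave as half-open
  a <- round(abs(rho), 10)
  names(magnitude_bands)[which(a < magnitude_bands)[1]]
}

#' Log-transformed Bland-Altman analysis
#'
#' Proportional agreement on the log-ratio scale: on `ln(device/criterion)`
#' the mean and `+/- 1.96 SD` limits are computed, then back-transformed to
#' percent differences via `100 * (exp(x) - 1)`. Pairs in which either
#' value does not exceed the positivity floor violate the log-ratio
#' assumptions and are excluded and counted; variables dominated by
#' negative or near-zero values (e.g. instantaneous acceleration) should
#' not be analysed this way at all.
#'
#' @param p A [paired_sample()].
#' @param floor Positivity floor in the variable's units.
#' @param multiplier LoA multiplier.
#' @return List: `percent_bias`, `percent_loa_low`, `percent_loa_high`,
#'   `n`, `n_excluded_nonpositive`.
#' @export
log_bland_altman <- function(p, floor = 1e-6, multiplier = 1.96) {
  ok <- p$device > floor & p$criterion > floor
  n_excl <- sum(!ok)
  q <- p[ok, ]
  if (nrow(q) < 2) stop("fewer than 2 positive pairs for log Bland-Altman", call. = FALSE)
  r <- log(q$device / q$criterion)
  b <- mean(r)
  s <- sd(r)
  pct <- function(x) 100 * (exp(x) - 1)
  list(
    percent_bias = pct(b),
    percent_loa_low = pct(b - multiplier * s),
    percent_loa_high = pct(b + multiplier * s),
    n = nrow(q), n_excluded_nonpositive = n_excl
  )
}

#' Heteroscedasticity screen for Bland-Altman differences
#'
#' Spearman correlation between the absolute paired differences and the
#' pair means `(device + criterion) / 2`, with a two-sided significance
#' screen at `alpha`. A significant correlation indicates that the error
#' magnitude grows (or shrinks) with the size of the measurement. Zero
#' variance in either margin leaves the screen undefined and flagged.
#'
#' @param p A [paired_sample()] with at least 3 rows.
#' @param alpha Significance level of the screen.
#' @return List: `rho`, `p_value`, `verdict` (`"none_detected"`,
#'   `"detected"` or `NA` when flagged), `flagged`.
#' @export
heteroscedasticity_check <- function(p, alpha = 0.05) {
  if (nrow(p) < 3) stop("need at least 3 rows", call. = FALSE)
  a <- abs(pair_diffs(p))
  m <- (p$device + p$criterion) / 2
  if (sd(a) == 0 || sd(m) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_,
                verdict = NA_character_, flagged = TRUE))
  }
  ct <- suppressWarnings(cor.test(a, m, method = "spearman", exact = FALSE))
  verdict <- if (ct$p.value < alpha) "detected" else "none_detected"
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       verdict = verdict, flagged = FALSE)
}

#' Kolmogorov-Smirnov normality screen
#'
#' Tests a sample against normality. Because the mean and SD are estimated
#' from the sample, the Lilliefors-corrected statistic is used by default;
#' `lilliefors = FALSE` gives the uncorrected one-sample KS test against a
#' normal with the sample moments. A zero-variance sample is degenerate:
#' flagged and reported non-normal.
#'
#' @param x Numeric sample with at least 5 values.
#' @param alpha Significance level.
#' @param lilliefors Apply the Lilliefors correction for estimated
#'   parameters.
#' @return List: `statistic`, `p_value`, `normal`, `flagged`.
#' @export
ks_normality <- function(x, alpha = 0.05, lilliefors = TRUE) {
  if (length(x) < 5) stop("need at least 5 values", call. = FALSE)
  if (sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                normal = FALSE, flagged = TRUE))
  }
  ht <- if (lilliefors) {
    nortest::lillie.test(x)
  } else {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), sd(x)))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       normal = ht$p.value >= alpha, flagged = FALSE)
}

#' Full agreement battery for one paired sample
#'
#' Convenience wrapper computing every agreement statistic for one
#' variable: per-system mean and SD, MAE, RMSE, mean bias with 95% LoA in
#' the requested mode, Spearman correlation with magnitude label, and the
#' heteroscedasticity screen.
#'
#' @param p A [paired_sample()].
#' @param loa_mode `"pooled"` or `"first_trial"`.
#' @return A one-row tibble.
#' @export
agreement_summary <- function(p, loa_mode = "pooled") {
  ba <- mean_bias_loa(p, mode = loa_mode)
  sp <- spearman_with_magnitude(p)
  tibble::tibble(
    variable = attr(p, "variable") %||% "value",
    units = attr(p, "units") %||% "",
    loa_mode = loa_mode,
    device_mean = mean(p$device), device_sd = sd(p$device),
    criterion_mean = mean(p$criterion), criterion_sd = sd(p$criterion),
    mae = mae(p), rmse = rmse(p),
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    rho = sp$rho, rho_magnitude = sp$magnitude %||% NA_character_,
    n_pairs = nrow(p), n_loa = ba$n,
    n_trials = length(unique(paste(p$participant_id, p$trial_id)))
  )
}
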