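# Small-but-realistic parameter sets used across tests. Unit tests shorten
# the approach/run-out to keep trials cheap; acceptance-level checks use the
# package defaults.

fast_params <- function(...) {
  sprint_params(approach_length = 8, ...)
}

noise_only_error_model <- function(lag = 0) {
  # default noise magnitudes, no systematic error
  device_error_model(
    velocity_bias = 0, velocity_scale = 1,
    lag = lag,
    stride_length_bias = 0, stride_length_noise_sd = 0,
    event_jitter_sd = 0
  )
}

# smooth random signal for alignment tests (moving-average filtered walk)
smooth_signal <- function(n, seed) {
  withr::with_seed(seed, {
    x <- cumsum(rnorm(n + 400))
  })
  stats::filter(x, rep(1 / 21, 21), sides = 2)[201:(200 + n)]
}

series_value_at_oracle <- function(s, t) {
  approx(s$time, s$value, xout = t)$y
}

random_paired_sample <- function(n, seed) {
  withr::with_seed(seed, {
    crit <- rnorm(n, 10, 2)
    dev <- crit + rnorm(n, -0.3, 0.8)
    paired_sample(
      participant_id = sample(1:5, n, replace = TRUE),
      trial_id = sample(1:4, n, replace = TRUE),
      device = dev, criterion = crit
    )
  })
}
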