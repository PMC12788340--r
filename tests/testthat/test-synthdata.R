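test_that("stance windows follow the duty-factor convention", {
  p <- fast_params(duty_factor = 0.25, stride_frequency = 2)
  tr <- simulate_criterion_trial(p)
  for (ft in c("left", "right")) {
    ev <- tr$true_events[tr$true_events$foot == ft, ]
    on <- sort(ev$time[ev$kind == "foot_strike"])
    off <- sort(ev$time[ev$kind == "toe_off"])
    expect_equal(off - on, rep(0.125, length(on)), tolerance = 1e-12)
    # same-foot stances never overlap
    expect_true(all(diff(on) > 0.125))
  }
})

test_that("GRF is exactly zero outside stance and peaks above body weight", {
  p <- fast_params()
  tr <- simulate_criterion_trial(p)
  dt <- 1 / tr$grf_rate
  for (ft in c("left", "right")) {
    g <- tr$grf[tr$grf$foot == ft, ]
    ev <- tr$true_events[tr$true_events$foot == ft, ]
    on <- sort(ev$time[ev$kind == "foot_strike"])
    off <- sort(ev$time[ev$kind == "toe_off"])
    in_stance <- rep(FALSE, nrow(g))
    for (k in seq_along(on)) {
      in_stance <- in_stance | (g$time > on[k] & g$time < off[k])
    }
    expect_true(all(g$fz[!in_stance] == 0))
    for (k in seq_along(on)) {
      bump <- g$fz[g$time > on[k] & g$time < off[k]]
      expect_gt(max(bump), p$body_weight)
      expect_gt(sum(bump) * dt, 0)
    }
  }
})

test_that("forward velocity follows the mono-exponential rise", {
  p <- fast_params(peak_velocity = 8, tau = 1, com_vert_amp = 0)
  expect_equal(true_resultant_velocity(p, 3) / 8, 1 - exp(-3), tolerance = 1e-12)
  expect_equal(true_resultant_velocity(p, 0), 0)
  # truth is zero before the sprint start
  expect_equal(true_resultant_velocity(p, -0.5), 0)
})

test_that("device markers are stationary in stance and advance in swing", {
  tr <- simulate_criterion_trial(fast_params())
  m <- tr$markers[tr$markers$marker == "left_device", ]
  tt <- m$frame / tr$mocap_rate
  ev <- tr$true_events[tr$true_events$foot == "left", ]
  on <- sort(ev$time[ev$kind == "foot_strike"])
  off <- sort(ev$time[ev$kind == "toe_off"])
  for (k in seq_along(on)) {
    xs <- m$x[tt >= on[k] & tt <= off[k]]
    expect_lt(diff(range(xs)), 1e-9)
  }
  # forward progress between consecutive stances
  mid <- vapply(seq_along(on), function(k) m$x[which.min(abs(tt - on[k]))], numeric(1))
  expect_true(all(diff(mid) > 0))
})

test_that("identity error model reproduces the subsampled truth", {
  tr <- simulate_criterion_trial(fast_params())
  dv <- degrade_to_device(tr, identity_error_model())
  expect_equal(dv$velocity$value,
               true_resultant_velocity(tr$params, dv$velocity$time),
               tolerance = 1e-12)
  expect_equal(dv$acceleration$value,
               true_resultant_acceleration(tr$params, dv$acceleration$time),
               tolerance = 1e-12)
  # stride records match the ground-truth strides exactly
  ts <- tr$true_strides
  expect_equal(nrow(dv$stride_records), nrow(ts))
  recs <- dv$stride_records[order(dv$stride_records$foot, dv$stride_records$time), ]
  tso <- ts[order(ts$foot, ts$end_time), ]
  expect_equal(recs$time, tso$end_time, tolerance = 1e-12)
  expect_equal(recs$length, tso$length, tolerance = 1e-12)
  expect_equal(recs$duration, tso$duration, tolerance = 1e-12)
})

test_that("a pure additive velocity bias shifts every sample exactly", {
  tr <- simulate_criterion_trial(fast_params())
  em <- device_error_model(velocity_bias = -0.5, velocity_scale = 1,
                           velocity_noise_sd = 0, accel_noise_sd = 0, lag = 0,
                           event_jitter_sd = 0, stride_length_bias = 0,
                           stride_length_noise_sd = 0)
  dv <- degrade_to_device(tr, em)
  d <- dv$velocity$value - true_resultant_velocity(tr$params, dv$velocity$time)
  expect_equal(mean(d), -0.5, tolerance = 1e-12)
  expect_lt(diff(range(d)), 1e-12)
})

test_that("an injected clock lag shows up at the cross-correlation peak", {
  tr <- simulate_criterion_trial(fast_params())
  em <- noise_only_error_model(lag = 0.3)
  em$velocity_noise_sd <- 0
  em$accel_noise_sd <- 0
  dv <- degrade_to_device(tr, em)
  td <- dv$velocity$time
  truth <- true_resultant_velocity(tr$params, td)
  # brute-force demeaned cross-correlation over candidate shifts
  shifts <- seq(-1, 1, by = 0.1)
  cc <- vapply(shifts, function(s) {
    shifted <- true_resultant_velocity(tr$params, td - s)
    a <- dv$velocity$value - mean(dv$velocity$value)
    b <- shifted - mean(shifted)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_equal(shifts[which.max(cc)], 0.3, tolerance = 1e-9)
})

test_that("cohorts have the requested size and participant jitter", {
  co <- generate_cohort(2, 2, params = fast_params(), seed = 5)
  expect_length(co, 4)
  expect_length(generate_cohort(1, 1, params = fast_params(), seed = 5), 1)
  vp <- vapply(co, function(pr) pr$criterion$params$peak_velocity, numeric(1))
  # different participants differ; same participant's trials differ only by
  # the small trial-level jitter
  expect_false(isTRUE(all.equal(vp[1], vp[3])))
  expect_error(generate_cohort(0, 1), "n_participants")
})

test_that("regeneration from the same seed is byte-identical on CSV", {
  ser <- function(seed) {
    co <- generate_cohort(1, 1, params = fast_params(), seed = seed)
    dir <- withr::local_tempdir()
    write_marker_csv(co[[1]]$criterion, file.path(dir, "m.csv"))
    write_grf_csv(co[[1]]$criterion, file.path(dir, "g.csv"))
    write_device_series_csv(co[[1]]$device$velocity, file.path(dir, "v.csv"))
    write_stride_records_csv(co[[1]]$device$stride_records, file.path(dir, "s.csv"))
    unname(tools::md5sum(file.path(dir, c("m.csv", "g.csv", "v.csv", "s.csv"))))
  }
  expect_identical(ser(123), ser(123))
  expect_false(identical(ser(123), ser(124)))
})

test_that("device series CSVs round-trip through the readers", {
  tr <- simulate_criterion_trial(fast_params())
  dv <- degrade_to_device(tr, device_error_model())
  dir <- withr::local_tempdir()
  fp <- file.path(dir, "v.csv")
  write_device_series_csv(dv$velocity, fp)
  back <- read_device_series_csv(fp)
  expect_equal(back$value, dv$velocity$value, tolerance = 1e-12)
  expect_equal(back$rate, dv$velocity$rate, tolerance = 1e-9)
})

test_that("parameter invariants are enforced", {
  expect_error(sprint_params(duty_factor = 1.2), "duty_factor")
  expect_error(sprint_params(peak_velocity = -1), "peak_velocity")
  expect_error(sprint_params(stride_frequency = 0), "stride_frequency")
  expect_error(device_error_model(velocity_noise_sd = -0.1), "sd fields")
})

test_that("the packaged cohort fixture matches its published counts", {
  fx <- load_cohort_fixture()
  expect_equal(nrow(fx$participants), 23)
  expect_equal(fx$totals$trials, 92)
  expect_equal(fx$totals$left_strides + fx$totals$right_strides, 265)
  expect_equal(fx$participants$sport[fx$participants$participant_id == 16],
               "Track and field")
  # corrupted totals row is detected
  raw <- readLines(system.file("extdata", "table1_cohort.csv", package = "strideval"))
  raw[length(raw)] <- "Total,,93,132,133"
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(raw, bad)
  expect_error(load_cohort_fixture(bad), "corrupted")
})
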