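test_that("tap frames come from the printed duration statistics", {
  # degenerate SD: always the rounded mean duration
  m2 <- tap_time_model(c(209, 0), c(280, 0))
  expect_equal(unique(sample_tap_frame(50, m2)), 59L)
  m5 <- tap_time_model(c(239, 0), c(260, 0))
  expect_equal(unique(sample_tap_frame(50, m5)), 60L)
  # truncation bounds hold for any seed
  set.seed(3)
  f <- sample_tap_frame(5000, tap_time_model(c(200, 150), c(250, 150)))
  expect_true(all(f >= 24 & f <= 120))
})

test_that("session simulation is deterministic given its seed", {
  a <- simulate_drift_session(n_trials = 40, seed = 123)
  b <- simulate_drift_session(n_trials = 40, seed = 123)
  expect_identical(a, b)
  c5a <- simulate_accel_session(seed = 9)
  c5b <- simulate_accel_session(seed = 9)
  expect_identical(c5a, c5b)
})

test_that("carry-over of the estimate produces a previous-trial influence", {
  r <- simulate_experiment2(n_sessions = 25, n_trials = 300, seed = 31)
  # with slow updating the previous trial's velocity leaks into the error
  expect_gt(r$influence, 0.5)
  expect_lt(r$influence, 2.5)
  # without carry-over (estimate reset each trial) the influence vanishes:
  # emulate with w = 1 (the estimate is always the latest step)
  r1 <- simulate_experiment2(n_sessions = 25, n_trials = 300,
                             params = accumulator_params(1), seed = 31)
  expect_lt(abs(r1$influence), 3 * sd(r1$per_session[, 1]) / sqrt(25))
})

test_that("a frozen position-only model leaves only uncorrected recent steps", {
  # with a negligible update weight and zero initial estimate the predicted
  # error is T(tap-12) - T(tap): steps within the delay window shift the
  # error by their full size, earlier steps not at all
  sch <- list(step_options = c(-5, 5) / 3, probabilities = c(0.5, 0.5),
              mean_velocity = 0)
  sessions <- lapply(1:10, function(s) {
    simulate_drift_session(n_trials = 800, scheme = sch,
                           params = accumulator_params(1e-9),
                           tap_model = tap_time_preset(1),
                           initial_v = 0, seed = 100 + s, keep_steps = TRUE)
  })
  cur <- step_error_curve(sessions, offsets_frames = c(3, 8, 12, 13, 20, 30))
  within <- cur$offset_frames <= 12
  expect_equal(cur$error_diff[within], rep(-10 / 3, sum(within)),
               tolerance = 0.17)
  expect_lt(max(abs(cur$error_diff[!within])), 0.55)
})

test_that("the ignoring-acceleration sign convention is oriented correctly", {
  specs <- exp5_trajectory_specs()
  p <- accumulator_params(0.15)
  blocks <- make_session_blocks(5)
  ses <- simulate_accel_session(blocks, params = p, seed = 5)
  # per trial: recompute the screen-frame error and check the flip
  for (i in c(1, 50, 120)) {
    sp <- specs[[ses$spec_id[i]]]
    expect_equal(ses$signed_error[i],
                 -sp$direction * sp$accel_class * ses$error[i])
  }
  # the fast-updating model still lags a constantly changing velocity, so
  # the mean signed error is positive (behind accelerating targets, ahead of
  # decelerating ones)
  expect_gt(mean(ses$signed_error), 0)
})

test_that("learning curves bin trials 4 at a time within block pairs", {
  r <- simulate_experiment5(n_experiments = 6, params = accumulator_params(0.15),
                            learning = learning_params(), seed = 77)
  lc <- learning_curves(r$trials)
  pairs <- c("acceleration", "direction", "error", "speed")
  expect_setequal(lc$pair, c(pairs, "reference"))
  for (p in pairs) expect_equal(sort(lc$bin[lc$pair == p]), 1:3)
  expect_true(is.na(lc$bin[lc$pair == "reference"]))
  expect_equal(unique(lc$n_sessions), 6)
  # with learning disabled the curves are flat across bins
  r0 <- simulate_experiment5(n_experiments = 12, params = accumulator_params(0.15),
                             seed = 78)
  lc0 <- learning_curves(r0$trials)
  for (p in pairs) {
    v <- lc0$mean_error[lc0$pair == p]
    se <- max(lc0$sd_error[lc0$pair == p]) / sqrt(12)
    expect_lt(diff(range(v)), 4 * se + 0.5)
  }
})
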