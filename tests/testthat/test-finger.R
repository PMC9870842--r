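test_that("minimum-jerk responses start and end at rest and conserve displacement", {
  expect_equal(min_jerk_velocity(3.33, 0.2, 0), 0)
  expect_equal(min_jerk_velocity(3.33, 0.2, 1), 0)
  # the velocity integrates to exactly D (int 30 t^2 (1-t)^2 dt = 1)
  for (D in c(3.33, -6.67)) {
    for (T_s in c(0.05, 0.2)) {
      q <- integrate(function(u) min_jerk_velocity(D, T_s, u) * T_s, 0, 1,
                     rel.tol = 1e-10)
      expect_equal(q$value, D, tolerance = 1e-8)
    }
  }
  # peak at the midpoint equals 1.875 D / T (grid-max oracle)
  D <- 3.33; T_s <- 0.16
  grid <- seq(0, 1, by = 1e-4)
  v <- min_jerk_velocity(D, T_s, grid)
  expect_equal(max(v), 1.875 * D / T_s, tolerance = 1e-6)
  expect_equal(grid[which.max(v)], 0.5, tolerance = 1e-3)
  expect_error(min_jerk_velocity(1, -0.1, 0.5), "positive")
})

test_that("the damping regime switches exactly at the critical available time", {
  Tc <- msd_critical_T()
  expect_equal(Tc, (3800 - 75^2 / 4) / 16)
  expect_equal(round(Tc / 10) * 10, 150) # underdamped below about 150 ms
  b <- 75
  expect_lt(b^2 - 4 * msd_stiffness(Tc - 1), 0)
  expect_gt(b^2 - 4 * msd_stiffness(Tc + 1), 0)
  expect_equal(msd_response(1, Tc - 1, 0.1)$regime, "underdamped")
  expect_equal(msd_response(1, Tc + 1, 0.1)$regime, "overdamped")
  expect_error(msd_stiffness(300), "positive")
})

test_that("closed-form MSD responses match a numeric ODE solution", {
  skip_if_not_installed("deSolve")
  times <- seq(0, 0.3, by = 0.002)
  for (T_ms in c(60, 100, 148, 151, 200)) {
    cf <- msd_response(3.33, T_ms, times)
    ode <- msd_ode_oracle(3.33, T_ms, times)
    expect_lt(sqrt(mean((cf$x - ode$x)^2)), 1e-6)
    expect_lt(sqrt(mean((cf$velocity - ode$velocity)^2)), 1e-6)
  }
})

test_that("underdamped responses overshoot and reverse; D = 0 stays at rest", {
  t <- seq(0, 0.4, by = 0.001)
  r <- msd_response(3.33, 100, t)
  expect_lt(min(r$x), 0) # crosses through the target
  expect_lt(min(r$velocity), 0) # and the response velocity reverses
  expect_equal(msd_response(0, 100, t)$velocity, rep(0, length(t)))
})

test_that("MSD corrections settle by the tap when enough time is available", {
  # closed-form settling horizon at the stiffness cap (k = 600 s^-2): the
  # slow eigenvalue is ~9.1 s^-1, so ~350 ms leaves < 5% of the step
  r <- msd_response(3.33, 200, 0.35)
  expect_lt(abs(r$x) / 3.33, 0.05)
  # isolated early steps (>= 450 ms before the tap) are corrected in full:
  # the finger ends on the target despite the mid-trial excursion
  steps <- rep(0, 69)
  steps[8] <- 3.33
  steps[12] <- -3.33
  traj <- target_trajectory(steps)
  tr <- synthesize_trial(traj, 70, movement_time = 0.35, model = "msd",
                         noise_sd = 0)
  x_tap <- tr$x[attr(tr, "tap_index")]
  expect_equal(x_tap, traj$positions[70], tolerance = 0.05 * 3.33)
  # ... and the excursion did happen (the finger followed the step up)
  expect_gt(max(tr$x), 0.3)
})

test_that("synthesis is superposable and silent without jitter", {
  # no jitter: the lateral path is exactly the transport profile
  traj0 <- target_trajectory(rep(5, 69))
  tr0 <- synthesize_trial(traj0, 70, movement_time = 0.3, noise_sd = 0,
                          expected_step = 5)
  s <- pmin(pmax((tr0$time - (attr(tr0, "tap_time") - 0.3)) / 0.3, 0), 1)
  expect_equal(tr0$x, min_jerk_position(5 * 69, s), tolerance = 1e-9)
  # responses to two steps superpose (linear models)
  base <- rep(0, 69)
  s1 <- base; s1[20] <- 2
  s2 <- base; s2[30] <- -3
  s12 <- base; s12[20] <- 2; s12[30] <- -3
  syn <- function(st) {
    # expected step 0: the lateral path is purely the superposed responses
    tr <- synthesize_trial(target_trajectory(st), 70, movement_time = 0.3,
                           model = "msd", noise_sd = 0)
    tr$x
  }
  expect_equal(syn(s12), syn(s1) + syn(s2), tolerance = 1e-6)
})

test_that("synthesized trials carry a detectable impact", {
  tr <- synthesize_trial(make_random_walk(60, seed = 2), 60,
                         movement_time = 0.29, noise_sd = 0)
  expect_s3_class(tr, "finger_trial")
  expect_equal(median(diff(tr$time)), 0.002)
  tap <- detect_tap(tr)
  expect_equal(tap$mode, "acceleration")
  expect_equal(tap$tap_index, attr(tr, "tap_index"), tolerance = 1)
})
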