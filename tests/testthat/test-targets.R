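test_that("positions are the exact integral of the steps", {
  for (seed in 1:5) {
    tr <- make_random_walk(60, seed = seed)
    expect_identical(tr$positions, tr$positions[1] + c(0, cumsum(tr$steps)))
    expect_equal(diff(tr$positions), tr$step_velocities * 1 / 120)
    expect_length(tr$positions, 60)
    expect_length(tr$steps, 59)
  }
})

test_that("random-walk steps have the speed the step size implies", {
  tr <- make_random_walk(80, step_length = step_from_speed(20), seed = 3)
  expect_true(all(abs(abs(tr$step_velocities) - 200) < 1e-12))
  # degenerate single-frame trajectory
  tr1 <- make_random_walk(1, seed = 1)
  expect_length(tr1$positions, 1)
  expect_length(tr1$steps, 0)
  expect_error(make_random_walk(0), "n_frames")
})

test_that("random-walk final positions match the closed-form moments", {
  # closed form: mean 0, variance n_steps * step^2
  n <- 1e5L
  nf <- 60L
  step <- step_from_speed(20)
  set.seed(42)
  finals <- colSums(matrix(sample(c(-1, 1), n * (nf - 1), replace = TRUE),
                           nf - 1, n)) * step
  se_mean <- sd(finals) / sqrt(n)
  expect_lt(abs(mean(finals)), 3 * se_mean)
  expect_equal(var(finals), (nf - 1) * step^2, tolerance = 0.02)
})

test_that("drifting walk honours prefix, options and probabilities", {
  sch <- variability_scheme("standard")
  tr <- make_drifting_walk(60, sch$step_options, sch$probabilities, seed = 9)
  expect_true(all(tr$step_velocities %in% c(400, 800)))
  expect_equal(mean(sch$step_options) * 120, 600)
  # deterministic prefix is reproduced verbatim
  pre <- rep(step_from_speed(40), 12)
  tr2 <- make_drifting_walk(60, sch$step_options, fixed_prefix = pre,
                            start_pos = -180, seed = 9)
  expect_equal(tr2$steps[1:12], pre)
  expect_error(make_drifting_walk(60, c(1, 2), probabilities = c(0.7, 0.7)),
               "sum to 1")
  expect_error(make_drifting_walk(5, c(1), fixed_prefix = rep(1, 10)), "prefix")
})

test_that("fast and slow initial-speed prefixes meet at the same position", {
  # slow prefix from -180 mm and fast prefix from -220 mm coincide at frame 13
  slow <- make_drifting_walk(60, variability_scheme("standard")$step_options,
                             fixed_prefix = rep(step_from_speed(40), 12),
                             start_pos = -180, seed = 5)
  fast <- make_drifting_walk(60, variability_scheme("standard")$step_options,
                             fixed_prefix = rep(step_from_speed(80), 12),
                             start_pos = -220, seed = 5)
  expect_equal(slow$positions[13], -140)
  expect_equal(fast$positions[13], -140)
})

test_that("variability schemes give the printed speed pairs", {
  expect_equal(variability_scheme("none")$speeds_cm_s, 60)
  expect_equal(variability_scheme("small")$speeds_cm_s, c(50, 70))
  expect_equal(variability_scheme("standard")$speeds_cm_s, c(40, 80))
  expect_equal(variability_scheme("large")$speeds_cm_s, c(25, 95))
  expect_equal(variability_scheme("standard")$step_options, c(10, 20) / 3)
  # large: per-step speed SD is half the spread about the 60 cm/s mean
  lg <- variability_scheme("large")
  expect_equal(sqrt(mean((lg$speeds_cm_s - 60)^2)), 35)
  expect_error(variability_scheme("huge"))
})

test_that("initial speeds satisfy the 700 ms kinematic constraint", {
  specs <- exp5_trajectory_specs()
  expect_length(specs, 8)
  for (sp in specs) {
    # oracle: forward-integrate the continuous kinematics on a fine grid
    tt <- seq(0, 0.7, by = 1e-5)
    v <- sp$v0 + sp$accel_along * tt
    travelled <- sum(v) * 1e-5
    expect_equal(travelled, sp$initial_offset + 300, tolerance = 1e-3)
    expect_equal(sign(sp$start_pos), -sp$direction)
  }
  # fast minus slow initial speed, same acceleration sign
  expect_equal(specs$right_accel_fast$v0 - specs$right_accel_slow$v0, 100 / 0.7)
  # zero-acceleration limit
  sp0 <- accel_spec(1, 1, "slow")
  sp0$accel_along <- 0
  expect_equal(solve_initial_speed(sp0), 600 / 0.7)
})

test_that("accelerating trajectories integrate the continuous kinematics exactly", {
  specs <- exp5_trajectory_specs()
  for (sp in specs) {
    tr <- make_accel_trajectory(sp, 120)
    # frame-midpoint velocities make frame positions exact: check at 700 ms
    expect_equal(tr$positions[85], sp$direction * 300, tolerance = 1e-9)
    # per-frame speed changes by a / 120
    dv <- diff(abs(tr$step_velocities))
    expect_equal(dv, rep(sp$accel_class * 400 / 120, length(dv)), tolerance = 1e-9)
  }
  # leftward spec mirrors the rightward one exactly
  r <- make_accel_trajectory(accel_spec(1, 1, "slow"), 100)
  l <- make_accel_trajectory(accel_spec(-1, 1, "slow"), 100)
  expect_equal(l$positions, -r$positions)
  # off-screen trajectories are flagged, not clipped
  tr_long <- make_accel_trajectory(accel_spec(1, 1, "fast"), 121)
  expect_false(is.null(attr(tr_long, "truncated_at")))
})

test_that("a session has 17 blocks and 168 trials with the right composition", {
  blocks <- make_session_blocks(7)
  expect_equal(nrow(blocks), 168)
  expect_equal(length(unique(blocks$block)), 17)
  ids <- names(exp5_trajectory_specs())
  for (b in unique(blocks$block)) {
    tb <- blocks[blocks$block == b, ]
    if (tb$block_kind[1] == "reference") {
      expect_equal(sort(tb$spec_id), sort(ids))
    } else {
      expect_equal(nrow(tb), 12)
      expect_equal(as.vector(table(tb$spec_id)), rep(3L, 4))
    }
  }
  # reference blocks alternate with experimental blocks
  kinds <- tapply(blocks$block_kind, blocks$block, `[`, 1)
  expect_equal(as.vector(kinds[seq(1, 17, 2)] == "reference"), rep(TRUE, 9))
  # error-grouped blocks: ignoring acceleration pushes the tap to one side,
  # so direction * acceleration sign is constant within the block
  specs <- exp5_trajectory_specs()
  for (nm in c("error_1", "error_2")) {
    tb <- blocks[blocks$block_kind == nm, ]
    dc <- vapply(specs[tb$spec_id],
                 function(s) s$direction * s$accel_class, 0)
    expect_equal(length(unique(dc)), 1L)
  }
})

test_that("alternating scenario alternates acceleration classes", {
  blocks <- make_alternating_blocks(6, seed = 2)
  expect_equal(nrow(blocks), 72)
  kinds <- tapply(blocks$block_kind, blocks$block, `[`, 1)
  expect_equal(as.vector(kinds), rep(c("alternating_accel", "alternating_decel"), 3))
  expect_true(all(grepl("^right", blocks$spec_id)))
})
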