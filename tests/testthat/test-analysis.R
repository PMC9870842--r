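test_that("the Savitzky-Golay stage is exact on polynomials up to order 2", {
  dt <- 0.002
  t <- (0:199) * dt
  # constant input
  k <- savgol_kinematics(rep(7, 200))
  expect_equal(k$position, rep(7, 200), tolerance = 1e-9)
  expect_equal(k$velocity, rep(0, 200), tolerance = 1e-6)
  # quadratic input: value and derivative recovered exactly, ends included
  x <- 3 * t^2 - 2 * t + 0.5
  k <- savgol_kinematics(x, dt)
  expect_equal(k$position, x, tolerance = 1e-9)
  expect_equal(k$velocity, 6 * t - 2, tolerance = 1e-6)
})

test_that("smoothing reduces the velocity noise of a white-noise input", {
  set.seed(6)
  x <- rnorm(400, sd = 0.5)
  k <- savgol_kinematics(x)
  raw_v <- diff(x) / 0.002
  expect_lt(var(k$velocity), var(raw_v))
})

test_that("short gaps are interpolated and long gaps rejected", {
  t <- (0:199) * 0.002
  x <- 2 * t
  x_gap <- x
  x_gap[50:53] <- NA # 8 ms gap
  k <- savgol_kinematics(x_gap)
  expect_equal(k$position, x, tolerance = 1e-6)
  x_bad <- x
  x_bad[50:70] <- NA # 42 ms gap
  expect_error(savgol_kinematics(x_bad), "gap")
  expect_error(savgol_kinematics(rep(NA_real_, 50)), "missing")
})

test_that("tap detection uses the impact and falls back for gentle landings", {
  dt <- 0.002
  t <- (0:299) * dt
  # hard landing: steady approach that stops dead at sample 250
  z <- pmax(30 - 150 * t, 0)
  trial <- data.frame(time = t, z = z)
  tap <- detect_tap(trial)
  expect_equal(tap$mode, "acceleration")
  expect_equal(tap$tap_index, 101, tolerance = 1)
  # gentle landing: velocity tapers smoothly to zero, no threshold crossing
  z2 <- 30 * (1 - sin(pi * t / max(t) / 2))^2 + 0.5
  tap2 <- detect_tap(data.frame(time = t, z = z2))
  expect_equal(tap2$mode, "z_minimum")
  expect_equal(tap2$tap_index, which.min(z2))
  # finger never near the screen
  expect_error(detect_tap(data.frame(time = t, z = z + 20)), "no tap")
})

test_that("exclusion rules drop planted violations and keep the rest", {
  batch <- get_msd_batch()[1:20]
  # plant a late tap and an over-long gap
  late <- batch[[1]]
  attr(late, "tap_time") <- 0.75
  gappy <- batch[[2]]
  gappy$x[100:120] <- NA # 42 ms
  ok_gap <- batch[[3]]
  ok_gap$x[100:104] <- NA # 10 ms, interpolated
  res <- exclude_trials(c(list(late, gappy, ok_gap), batch[4:10]))
  expect_equal(unname(res$report["late_tap"]), 1)
  expect_equal(unname(res$report["gap"]), 1)
  expect_equal(unname(res$report["retained"]), 8)
  expect_false(anyNA(res$trials[[1]]$x))
})

test_that("step-sorted sets differ by twice the step size after the step", {
  # Monte-Carlo on bare trajectories: before the queried step the sets are
  # balanced, from it onwards they differ by 2 x 1.67 mm on average
  n <- 4000L
  nf <- 60L
  trials <- lapply(1:n, function(i) {
    structure(list(), target = make_random_walk(nf, seed = i),
              tap_frame = nf)
  })
  o <- 25L # query the step landing 24 frames (200 ms) before the tap
  sp <- split_by_step(trials, o)
  pos <- vapply(trials, function(tr) attr(tr, "target")$positions,
                numeric(nf))
  dmean <- rowMeans(pos[, sp$high]) - rowMeans(pos[, sp$low])
  step <- 10 / 6
  se <- 2 * step * sqrt(nf) / sqrt(n) # generous bound on the MC error
  idx <- nf - o # position index from which the sets should differ
  expect_lt(max(abs(dmean[1:idx])), 3 * se)
  expect_equal(mean(dmean[(idx + 1):nf]), 2 * step, tolerance = 3 * se)
})

test_that("gain is invariant to scaling the response with the step size", {
  cv <- data.frame(offset_frames = 20, step_before_tap_ms = 158,
                   t_from_step = seq(0, 0.3, by = 0.002))
  cv$dvel <- sin(pi * cv$t_from_step / 0.3) * 10
  cv$dpos <- cumsum(cv$dvel) * 0.002
  cv2 <- cv
  cv2$dvel <- 2 * cv$dvel
  g1 <- peak_gain(cv, step_delta = 10 / 3)
  g2 <- peak_gain(cv2, step_delta = 20 / 3)
  expect_equal(g1$peak_gain, g2$peak_gain, tolerance = 1e-3)
})

test_that("the pipeline recovers the generative latency and response ordering", {
  trials <- get_msd_batch()
  offsets <- c(25L, 31L, 37L)
  curves <- response_curves(trials, offsets)
  # latency: the velocity difference stays flat for ~100 ms, then rises
  lat <- response_latency(curves[curves$offset_frames == 31L, ])
  expect_lt(abs(lat - 0.1), 1 / 120)
  # vigour: later steps (less remaining time) give higher peaks
  pg <- peak_gain(curves, step_delta = 10 / 3)
  expect_equal(order(pg$peak_response), c(3, 2, 1))
})

test_that("tapping-error differences reproduce the correction pattern", {
  trials <- get_msd_batch()
  offs <- c(5L, 10L, 31L, 49L)
  es <- error_split(trials, offs)
  # steps within the latency of the tap are not corrected at all: the
  # difference matches (twice) the step size
  expect_equal(es$error_diff[es$offset_frames <= 12], rep(-10 / 3, 2),
               tolerance = 0.25)
  # steps long before the tap are corrected nearly in full (the closed-form
  # remainder at this horizon is about 7% of the 3.33 mm set difference)
  expect_gt(es$error_diff[es$offset_frames == 49L], -0.8)
  expect_lt(es$error_diff[es$offset_frames == 49L], 0.3)
  # in between the correction is partial
  mid <- es$error_diff[es$offset_frames == 31L]
  expect_gt(mid, -10 / 3 + 0.5)
})

test_that("trial batches round-trip through the CSV/JSON files", {
  dir <- withr::local_tempdir()
  batch <- get_msd_batch()[1:5]
  write_trials(batch, dir, seed = 500)
  back <- read_trials(dir)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$x, batch[[i]]$x, tolerance = 1e-9)
    expect_equal(attr(back[[i]], "tap_frame"), attr(batch[[i]], "tap_frame"))
    expect_equal(attr(back[[i]], "target")$positions,
                 attr(batch[[i]], "target")$positions, tolerance = 1e-9)
  }
  # an orphaned trial is reported by id
  tg <- read.csv(file.path(dir, "targets.csv"))
  write.csv(tg[tg$trial_id != 3, ], file.path(dir, "targets.csv"),
            row.names = FALSE)
  expect_error(read_trials(dir), "orphan.*3")
})
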