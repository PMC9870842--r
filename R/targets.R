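#' Target trajectories
#'
#' Targets move only laterally, in discrete steps between consecutive frames
#' of a 120 Hz display. A trajectory stores the position shown on each frame
#' and the step applied between frames; positions are the exact cumulative
#' sum of the steps so that reconstructing one from the other is lossless.
#'
#' @param steps per-frame lateral displacements (mm), length `n_frames - 1`.
#' @param start_pos lateral position of the first frame (mm).
#' @param kinematics optional closed-form kinematic description (used by
#'   constant-acceleration trajectories) as a list with polynomial
#'   coefficients `x0`, `b`, `c` so that `x(t) = x0 + b t + c t^2`.
#' @return an object of class `target_trajectory` with fields `times`,
#'   `positions`, `steps`, `step_velocities`.
#' @export
target_trajectory <- function(steps, start_pos = 0, kinematics = NULL) {
  n_frames <- length(steps) + 1L
  positions <- start_pos + c(0, cumsum(steps))
  structure(
    list(
      times = (seq_len(n_frames) - 1) * FRAME_DT,
      positions = positions,
      steps = steps,
      step_velocities = steps * FRAME_HZ,
      n_frames = n_frames,
      kinematics = kinematics
    ),
    class = "target_trajectory"
  )
}

#' @export
print.target_trajectory <- function(x, ...) {
  cat(sprintf(
    "<target_trajectory> %d frames (%.0f ms), start %.1f mm, mean speed %.1f cm/s\n",
    x$n_frames, 1000 * (x$n_frames - 1) * FRAME_DT, x$positions[1],
    mean(x$step_velocities) / 10
  ))
  invisible(x)
}

#' Random-walk target (position jitter without systematic motion)
#'
#' Each frame the target steps a fixed distance leftward or rightward with
#' equal probability. The default step of 5/3 mm at 120 Hz corresponds to a
#' speed of 20 cm/s.
#'
#' @param n_frames number of displayed frames (>= 1).
#' @param step_length unsigned step length in mm per frame.
#' @param start_pos lateral start position (mm).
#' @param seed optional seed for the step directions.
#' @return a [target_trajectory()].
#' @export
make_random_walk <- function(n_frames, step_length = step_from_speed(20),
                             start_pos = 0, seed = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (step_length <= 0) stop("step_length must be positive", call. = FALSE)
  steps <- with_seed(seed, sample(c(-1, 1), max(n_frames - 1L, 0L), replace = TRUE)) *
    step_length
  target_trajectory(steps, start_pos)
}

#' Drifting-walk target (jitter superposed on systematic motion)
#'
#' Steps are drawn i.i.d. from `step_options` with the given probabilities,
#' optionally after a deterministic prefix (used for the 100 ms of uniformly
#' fast or slow initial motion).
#'
#' @param n_frames number of displayed frames.
#' @param step_options signed step lengths (mm per frame).
#' @param probabilities weights, non-negative, summing to 1; default uniform.
#' @param fixed_prefix step lengths imposed on the first frames.
#' @param start_pos lateral start position (mm).
#' @param seed optional seed.
#' @return a [target_trajectory()].
#' @export
make_drifting_walk <- function(n_frames, step_options,
                               probabilities = NULL,
                               fixed_prefix = numeric(0),
                               start_pos = 0, seed = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (length(step_options) == 0) stop("step_options must be non-empty", call. = FALSE)
  if (is.null(probabilities)) {
    probabilities <- rep(1 / length(step_options), length(step_options))
  }
  if (length(probabilities) != length(step_options)) {
    stop("probabilities and step_options must have equal length", call. = FALSE)
  }
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-8) {
    stop("probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  n_steps <- n_frames - 1L
  if (length(fixed_prefix) > n_steps) {
    stop("fixed_prefix longer than the number of steps", call. = FALSE)
  }
  n_random <- n_steps - length(fixed_prefix)
  random_steps <- with_seed(
    seed,
    step_options[sample.int(length(step_options), n_random, replace = TRUE,
                            prob = probabilities)]
  )
  target_trajectory(c(fixed_prefix, random_steps), start_pos)
}

#' Step-size variability schemes
#'
#' The four jitter-amplitude levels used when comparing responses across
#' blocks: the target always averages 60 cm/s rightward, with the two
#' equiprobable per-frame speeds differing by 0 (`none`), 20 (`small`),
#' 40 (`standard`) or 70 (`large`) cm/s.
#'
#' @param level one of `"none"`, `"small"`, `"standard"`, `"large"`.
#' @return a list with `speeds_cm_s`, `step_options` (mm/frame) and
#'   `probabilities`.
#' @export
variability_scheme <- function(level = c("none", "small", "standard", "large")) {
  level <- match.arg(level)
  speeds <- switch(level,
    none = 60,
    small = c(50, 70),
    standard = c(40, 80),
    large = c(25, 95)
  )
  list(
    level = level,
    speeds_cm_s = speeds,
    step_options = step_from_speed(speeds),
    probabilities = rep(1 / length(speeds), length(speeds)),
    mean_velocity = mean(speeds) * 10
  )
}

#' Constant-acceleration trajectory specification
#'
#' One of the eight accelerating/decelerating target kinds: the target moves
#' leftward or rightward, speeds up or slows down at 40 cm/s^2, and starts
#' either 30 cm (slow) or 40 cm (fast) from the screen centre on the side
#' opposite its motion. The initial speed is solved so that the target is
#' 32.5 cm from the approached edge of the 1.25 m screen (300 mm past the
#' centre) 700 ms after appearing.
#'
#' @param direction +1 rightward, -1 leftward.
#' @param accel_class +1 accelerating (speeding up), -1 decelerating.
#' @param speed `"slow"` or `"fast"` (initial offset 300 vs 400 mm).
#' @param accel_mag acceleration magnitude (mm/s^2).
#' @return a list of class `accel_spec`.
#' @export
accel_spec <- function(direction, accel_class, speed = c("slow", "fast"),
                       accel_mag = 400) {
  speed <- match.arg(speed)
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1", call. = FALSE)
  if (!accel_class %in% c(-1, 1)) stop("accel_class must be +1 or -1", call. = FALSE)
  offset <- if (speed == "slow") 300 else 400
  spec <- structure(
    list(
      direction = direction,
      accel_class = accel_class,
      speed = speed,
      accel_mag = accel_mag,
      accel_along = accel_class * accel_mag, # signed along the motion direction
      initial_offset = offset,
      start_pos = -direction * offset
    ),
    class = "accel_spec"
  )
  spec$v0 <- solve_initial_speed(spec)
  spec$id <- sprintf(
    "%s_%s_%s",
    if (direction > 0) "right" else "left",
    if (accel_class > 0) "accel" else "decel",
    speed
  )
  spec
}

#' Initial speed satisfying the 700 ms position constraint
#'
#' Solves `d = v0 * 0.7 + a * 0.7^2 / 2` where `d` is the distance from the
#' starting position to the point 300 mm past the screen centre and `a` the
#' signed acceleration along the motion direction.
#'
#' @param spec an [accel_spec()] (the `v0` field is ignored).
#' @return the initial speed in mm/s.
#' @export
solve_initial_speed <- function(spec) {
  t_c <- 0.7
  d <- spec$initial_offset + 300
  v0 <- (d - 0.5 * spec$accel_along * t_c^2) / t_c
  if (v0 <= 0) stop("no positive initial speed satisfies the constraint", call. = FALSE)
  v0
}

#' All eight constant-acceleration trajectory kinds
#'
#' @return a list of eight [accel_spec()] objects, named by their id.
#' @export
exp5_trajectory_specs <- function() {
  grid <- expand.grid(
    direction = c(1, -1), accel_class = c(1, -1), speed = c("slow", "fast"),
    stringsAsFactors = FALSE
  )
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    accel_spec(grid$direction[i], grid$accel_class[i], grid$speed[i])
  })
  names(specs) <- vapply(specs, `[[`, "", "id")
  specs
}

#' Constant-acceleration target trajectory
#'
#' The per-frame step uses the continuous velocity evaluated at the frame
#' midpoint, so the discrete positions coincide exactly with the continuous
#' kinematics at every frame time (and the 700 ms constraint holds exactly).
#'
#' @param spec an [accel_spec()].
#' @param n_frames number of displayed frames (default 120 frames = 1 s).
#' @return a [target_trajectory()]; if the target leaves the screen half-width
#'   before `n_frames`, attribute `truncated_at` records the first off-screen
#'   frame (the trajectory itself is not clipped).
#' @export
make_accel_trajectory <- function(spec, n_frames = 120L) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  k <- seq_len(n_frames - 1L)
  t_mid <- (k - 0.5) * FRAME_DT
  steps <- spec$direction * (spec$v0 + spec$accel_along * t_mid) * FRAME_DT
  kin <- list(
    x0 = spec$start_pos,
    b = spec$direction * spec$v0,
    c = spec$direction * spec$accel_along / 2,
    direction = spec$direction,
    accel_class = spec$accel_class,
    v0 = spec$v0,
    accel_along = spec$accel_along
  )
  traj <- target_trajectory(steps, spec$start_pos, kinematics = kin)
  off <- which(abs(traj$positions) > SCREEN_HALF_MM)
  if (length(off) > 0) attr(traj, "truncated_at") <- off[1]
  traj
}

#' Block structure of an acceleration session
#'
#' A session is 168 trials in 17 blocks: 9 reference blocks (each of the 8
#' trajectory kinds once, shuffled) alternating with the 8 experimental
#' blocks in random order. The experimental blocks form four pairs
#' (acceleration-, error-, speed- and direction-grouped); each block presents
#' its 4 trajectory kinds 3 times in random order.
#'
#' @param session_seed integer seed for the block and trial orders.
#' @return a data.frame with one row per trial: `trial`, `block`,
#'   `block_kind`, `pair`, `trial_in_block`, `spec_id`.
#' @export
make_session_blocks <- function(session_seed = NULL) {
  specs <- exp5_trajectory_specs()
  ids <- names(specs)
  is_accel <- vapply(specs, function(s) s$accel_class > 0, logical(1))
  is_right <- vapply(specs, function(s) s$direction > 0, logical(1))
  is_slow <- vapply(specs, function(s) s$speed == "slow", logical(1))
  # ignoring acceleration pushes the tap behind accelerating and ahead of
  # decelerating targets: in error-grouped blocks all four kinds push the tap
  # to the same screen side (right-decel with left-accel, or vice versa)
  pushes_right <- (is_right & !is_accel) | (!is_right & is_accel)
  exp_blocks <- list(
    acceleration_1 = ids[is_accel],
    acceleration_2 = ids[!is_accel],
    error_1 = ids[pushes_right],
    error_2 = ids[!pushes_right],
    speed_1 = ids[is_slow],
    speed_2 = ids[!is_slow],
    direction_1 = ids[is_right],
    direction_2 = ids[!is_right]
  )
  with_seed(session_seed, {
    order_exp <- sample(names(exp_blocks))
    rows <- list()
    for (b in 1:17) {
      if (b %% 2 == 1) {
        kind <- "reference"; pair <- "reference"
        trial_ids <- sample(ids)
      } else {
        nm <- order_exp[b / 2]
        kind <- nm
        pair <- sub("_[12]$", "", nm)
        trial_ids <- sample(rep(exp_blocks[[nm]], 3))
      }
      rows[[b]] <- data.frame(
        block = b, block_kind = kind, pair = pair,
        trial_in_block = seq_along(trial_ids), spec_id = trial_ids,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    out$trial <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("trial", "block", "block_kind", "pair", "trial_in_block", "spec_id")]
  })
}

#' Alternating accelerating/decelerating rightward blocks
#'
#' The replication scenario in which all targets move rightward and blocks of
#' 12 trials alternate between all-accelerating and all-decelerating (both
#' speeds, 6 trials each, shuffled within a block).
#'
#' @param n_blocks number of 12-trial blocks.
#' @param seed integer seed.
#' @return a data.frame in the same format as [make_session_blocks()].
#' @export
make_alternating_blocks <- function(n_blocks = 10L, seed = NULL) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_blocks), function(b) {
      cls <- if (b %% 2 == 1) "accel" else "decel"
      ids <- sprintf("right_%s_%s", cls, c("slow", "fast"))
      trial_ids <- sample(rep(ids, 6))
      data.frame(
        block = b, block_kind = paste0("alternating_", cls), pair = "alternating",
        trial_in_block = seq_along(trial_ids), spec_id = trial_ids,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$trial <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("trial", "block", "block_kind", "pair", "trial_in_block", "spec_id")]
  })
}
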