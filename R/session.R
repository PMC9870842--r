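#' Monte-Carlo session simulation
#'
#' Chains target generation, velocity accumulation and (optionally)
#' trial-to-trial error-correction learning across the trials of a session,
#' carrying the velocity estimate from each trial to the next. The number of
#' displayed frames per trial (and hence the number of accumulator updates
#' and the tap frame) is drawn from a truncated normal built from a session's
#' typical reaction and movement times, standing in for resampling real trial
#' durations.
#'
#' @name session-simulation
NULL

#' Tap-time model
#'
#' @param reaction_ms `c(mean, sd)` of the reaction time in ms.
#' @param movement_ms `c(mean, sd)` of the movement time in ms.
#' @return a list of class `tap_time_model`.
#' @export
tap_time_model <- function(reaction_ms, movement_ms) {
  stopifnot(length(reaction_ms) == 2, length(movement_ms) == 2,
            reaction_ms[1] > 0, movement_ms[1] > 0,
            reaction_ms[2] >= 0, movement_ms[2] >= 0)
  structure(list(reaction_ms = reaction_ms, movement_ms = movement_ms,
                 mean_ms = reaction_ms[1] + movement_ms[1],
                 sd_ms = sqrt(reaction_ms[2]^2 + movement_ms[2]^2)),
            class = "tap_time_model")
}

#' Typical tap-time models per session type
#'
#' Mean and SD of reaction and movement times for the five session designs
#' (jittering static target; drifting targets; drifting with fixed initial
#' speed; graded variability; accelerating targets).
#'
#' @param experiment integer 1..5.
#' @return a [tap_time_model()].
#' @export
tap_time_preset <- function(experiment) {
  switch(as.character(experiment),
    "1" = tap_time_model(c(233, 21), c(290, 58)),
    "2" = tap_time_model(c(209, 17), c(280, 36)),
    "3" = tap_time_model(c(211, 14), c(283, 46)),
    "4" = tap_time_model(c(210, 20), c(267, 42)),
    "5" = tap_time_model(c(239, 21), c(260, 40)),
    stop("unknown experiment", call. = FALSE)
  )
}

#' Draw tap frames
#'
#' Total durations are drawn from a normal with the model's combined mean and
#' SD, rounded to 120 Hz frames and clipped to `[24, 120]` frames
#' (200-1000 ms).
#'
#' @param n number of draws.
#' @param model a [tap_time_model()].
#' @param mean_shift_ms sensitivity shift added to the mean (ms).
#' @return integer vector of tap frames.
#' @export
sample_tap_frame <- function(n, model, mean_shift_ms = 0) {
  ms <- stats::rnorm(n, model$mean_ms + mean_shift_ms, model$sd_ms)
  frames <- as.integer(round(ms / (1000 / FRAME_HZ)))
  pmin(pmax(frames, 24L), 120L)
}

#' Simulate one session with a drifting-walk target
#'
#' Used for the designs in which the target drifts rightward with jittered
#' step sizes (optionally with a deterministic fast/slow prefix). Each trial
#' draws a tap frame, generates the steps actually shown, runs the
#' accumulator (carrying the estimate across trials) and records the
#' model-predicted tapping error.
#'
#' @param n_trials number of trials.
#' @param scheme a [variability_scheme()] (or compatible list with
#'   `step_options`, `probabilities`, `mean_velocity`).
#' @param params an [accumulator_params()].
#' @param tap_model a [tap_time_model()].
#' @param initial_v velocity estimate at session start (mm/s); defaults to
#'   the scheme's mean velocity.
#' @param prefix_options optional list of deterministic step prefixes, one of
#'   which is chosen per trial with equal probability (fixed initial speed
#'   designs); `NULL` for fully random steps.
#' @param seed session seed; each trial derives its own stream.
#' @param keep_steps retain each trial's step vector (needed for
#'   [step_error_curve()]).
#' @return a data.frame with one row per trial: `trial`, `tap_frame`,
#'   `error`, `mean_v`, `last200_v`, `v_delay`, `final_v`, `prefix` (index
#'   into `prefix_options`, or NA); with `keep_steps`, attribute `steps` is
#'   the list of step vectors.
#' @export
simulate_drift_session <- function(n_trials = 500,
                                   scheme = variability_scheme("standard"),
                                   params = accumulator_params(0.02),
                                   tap_model = tap_time_preset(2),
                                   initial_v = NULL,
                                   prefix_options = NULL,
                                   seed = NULL,
                                   keep_steps = FALSE) {
  if (is.null(initial_v)) initial_v <- scheme$mean_velocity
  seed <- if (is.null(seed)) sample.int(2^31 - 1, 1) else seed
  v <- initial_v
  out <- data.frame(
    trial = seq_len(n_trials), tap_frame = NA_integer_, error = NA_real_,
    mean_v = NA_real_, last200_v = NA_real_, v_delay = NA_real_,
    final_v = NA_real_, prefix = NA_integer_
  )
  steps_log <- if (keep_steps) vector("list", n_trials) else NULL
  for (i in seq_len(n_trials)) {
    ts <- derive_seed(seed, i)
    set.seed(ts)
    tap <- sample_tap_frame(1, tap_model)
    pre_idx <- NA_integer_
    prefix <- numeric(0)
    if (!is.null(prefix_options)) {
      pre_idx <- sample.int(length(prefix_options), 1)
      prefix <- prefix_options[[pre_idx]]
    }
    n_random <- tap - 1L - length(prefix)
    steps <- c(prefix,
               scheme$step_options[sample.int(length(scheme$step_options),
                                              n_random, replace = TRUE,
                                              prob = scheme$probabilities)])
    traj <- target_trajectory(steps)
    acc <- run_trial_accumulation(traj, tap, params, v)
    v <- acc$final_v
    n_last <- min(24L, tap - 1L) # last 200 ms of target motion
    out$tap_frame[i] <- tap
    out$error[i] <- acc$predicted_error
    out$mean_v[i] <- mean(traj$step_velocities)
    out$last200_v[i] <- mean(traj$step_velocities[(tap - n_last):(tap - 1L)])
    out$v_delay[i] <- acc$v_delay
    out$final_v[i] <- acc$final_v
    out$prefix[i] <- pre_idx
    if (keep_steps) steps_log[[i]] <- steps
  }
  if (keep_steps) attr(out, "steps") <- steps_log
  out
}

#' Influence of the previous trial on the predicted error
#'
#' Splits current-trial errors by properties of the previous trial: its mean
#' target velocity (above vs below the scheme mean, ties dropped), its mean
#' velocity during the last 200 ms, and the sign of its error. First trials
#' of a session are skipped.
#'
#' @param session a data.frame from [simulate_drift_session()].
#' @param mean_velocity the scheme's mean velocity (mm/s).
#' @return named numeric vector of the three error differences (mm):
#'   `by_prev_mean_v`, `by_prev_last200_v`, `by_prev_error_sign`.
#' @export
previous_trial_influence <- function(session, mean_velocity = 600) {
  n <- nrow(session)
  cur <- session$error[-1]
  prev_mean <- session$mean_v[-n]
  prev_last <- session$last200_v[-n]
  prev_err <- session$error[-n]
  split_diff <- function(value, ref) {
    hi <- value > ref
    lo <- value < ref
    if (!any(hi) || !any(lo)) return(NA_real_)
    mean(cur[hi]) - mean(cur[lo])
  }
  c(
    by_prev_mean_v = split_diff(prev_mean, mean_velocity),
    by_prev_last200_v = split_diff(prev_last, mean_velocity),
    # tapping to the left of the target makes one aim further right next time,
    # so the difference is reported as (after leftward error) - (after rightward)
    by_prev_error_sign = {
      hi <- prev_err < 0
      lo <- prev_err > 0
      if (!any(hi) || !any(lo)) NA_real_ else mean(cur[hi]) - mean(cur[lo])
    }
  )
}

#' Simulate many drifting-target sessions
#'
#' @param n_sessions number of independent sessions.
#' @inheritParams simulate_drift_session
#' @return list with `influence` (mean of the per-session previous-trial
#'   velocity split differences, mm), `per_session` (matrix of the three
#'   splits per session) and `n_trials`.
#' @export
simulate_experiment2 <- function(n_sessions = 200, n_trials = 500,
                                 params = accumulator_params(0.02),
                                 tap_model = tap_time_preset(2),
                                 scheme = variability_scheme("standard"),
                                 seed = NULL) {
  seed <- if (is.null(seed)) sample.int(2^31 - 1, 1) else seed
  per <- t(vapply(seq_len(n_sessions), function(s) {
    ses <- simulate_drift_session(
      n_trials = n_trials, scheme = scheme, params = params,
      tap_model = tap_model, seed = derive_seed(seed, s)
    )
    previous_trial_influence(ses, scheme$mean_velocity)
  }, numeric(3)))
  list(
    influence = mean(per[, "by_prev_mean_v"], na.rm = TRUE),
    per_session = per,
    n_trials = n_trials, n_sessions = n_sessions
  )
}

#' Simulate one accelerating-target session
#'
#' Runs the aiming model over a blocked session of constant-acceleration
#' targets, carrying the velocity estimate across trials and optionally
#' applying spatial/temporal error-correction learning. Errors are also
#' reported with the sign convention that positive errors are consistent
#' with ignoring the acceleration (behind accelerating targets, ahead of
#' decelerating ones).
#'
#' @param blocks a trial table from [make_session_blocks()] or
#'   [make_alternating_blocks()]; generated from the seed if `NULL`.
#' @param params an [accumulator_params()].
#' @param learning a [learning_params()], or `NULL` to disable learning.
#' @param tap_model a [tap_time_model()].
#' @param initial_v velocity estimate at session start (mm/s); 0 by default
#'   since motion directions alternate.
#' @param mean_shift_ms tap-time sensitivity shift (ms).
#' @param seed session seed.
#' @return the trial table with added columns `tap_frame`, `error` (screen
#'   frame, mm), `signed_error` (ignoring-acceleration convention, mm),
#'   `C_s`, `C_t` (state used on that trial), `v_delay`, `final_v`.
#' @export
simulate_accel_session <- function(blocks = NULL,
                                   params = accumulator_params(0.02),
                                   learning = NULL,
                                   tap_model = tap_time_preset(5),
                                   initial_v = 0,
                                   mean_shift_ms = 0,
                                   seed = NULL) {
  seed <- if (is.null(seed)) sample.int(2^31 - 1, 1) else seed
  if (is.null(blocks)) blocks <- make_session_blocks(derive_seed(seed, 0))
  specs <- exp5_trajectory_specs()
  n <- nrow(blocks)
  out <- blocks
  out$tap_frame <- NA_integer_
  out$error <- NA_real_
  out$signed_error <- NA_real_
  out$C_s <- NA_real_
  out$C_t <- NA_real_
  out$v_delay <- NA_real_
  out$final_v <- NA_real_
  v <- initial_v
  state <- correction_state()
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    tap <- sample_tap_frame(1, tap_model, mean_shift_ms)
    spec <- specs[[blocks$spec_id[i]]]
    traj <- make_accel_trajectory(spec, n_frames = 121L)
    acc <- run_trial_accumulation(traj, tap, params, v)
    t_tap <- (tap - 1L) * FRAME_DT
    if (is.null(learning)) {
      err <- acc$predicted_error
    } else {
      A_tap <- corrected_aim_point(
        traj$positions[tap - params$delay_frames], acc$v_delay,
        t = t_tap, t_tap = t_tap, delta = params$delay_s, state = state
      )
      err <- A_tap - traj$positions[tap]
      te <- timing_error(traj, A_tap, t_tap)
      out$C_s[i] <- state$C_s
      out$C_t[i] <- state$C_t
      state <- update_spatial(state, err, learning)
      if (is.finite(te$timing_error)) {
        state <- update_temporal(state, te$timing_error, learning)
      }
    }
    out$tap_frame[i] <- tap
    out$error[i] <- err
    out$signed_error[i] <- -spec$direction * spec$accel_class * err
    out$v_delay[i] <- acc$v_delay
    out$final_v[i] <- acc$final_v
    v <- acc$final_v
  }
  out
}

#' Simulate many accelerating-target experiments
#'
#' @param n_experiments number of independent simulated sessions.
#' @inheritParams simulate_accel_session
#' @param scenario `"session"` for the 168-trial blocked design,
#'   `"alternating"` for the alternating accelerating/decelerating rightward
#'   scenario.
#' @param n_blocks blocks per session for the alternating scenario.
#' @param seed master seed.
#' @return list with `mean_signed` (all trials), `mean_signed_reference`
#'   (reference blocks only, session scenario), and `trials` (combined trial
#'   table with a `session` column).
#' @export
simulate_experiment5 <- function(n_experiments = 100,
                                 params = accumulator_params(0.02),
                                 learning = NULL,
                                 tap_model = tap_time_preset(5),
                                 scenario = c("session", "alternating"),
                                 n_blocks = 10L,
                                 initial_v = NULL,
                                 mean_shift_ms = 0,
                                 seed = NULL) {
  scenario <- match.arg(scenario)
  seed <- if (is.null(seed)) sample.int(2^31 - 1, 1) else seed
  sessions <- lapply(seq_len(n_experiments), function(s) {
    s_seed <- derive_seed(seed, s)
    if (scenario == "session") {
      blocks <- make_session_blocks(derive_seed(s_seed, 0))
      iv <- if (is.null(initial_v)) 0 else initial_v
    } else {
      blocks <- make_alternating_blocks(n_blocks, derive_seed(s_seed, 0))
      # all targets move rightward: start from the mean signed initial speed
      iv <- if (is.null(initial_v)) {
        specs <- exp5_trajectory_specs()
        mean(vapply(specs[grep("^right", names(specs))], `[[`, 0, "v0"))
      } else {
        initial_v
      }
    }
    ses <- simulate_accel_session(
      blocks = blocks, params = params, learning = learning,
      tap_model = tap_model, initial_v = iv, mean_shift_ms = mean_shift_ms,
      seed = s_seed
    )
    ses$session <- s
    ses
  })
  trials <- do.call(rbind, sessions)
  ref <- trials$block_kind == "reference"
  list(
    mean_signed = mean(trials$signed_error),
    mean_signed_reference = if (any(ref)) mean(trials$signed_error[ref]) else NA_real_,
    trials = trials,
    n_experiments = n_experiments
  )
}

#' Binned learning curves per block pair
#'
#' Within each 12-trial experimental block, signed errors are binned into
#' three sets of 4 consecutive trials. Within each session the median signed
#' error per (pair, bin) is taken over that session's trials, and the medians
#' are then averaged across sessions; reference blocks contribute a single
#' pooled median per session.
#'
#' @param trials combined trial table from [simulate_experiment5()].
#' @return a data.frame with `pair`, `bin`, `mean_error`, `sd_error` (across
#'   sessions) and `n_sessions`; the reference row has `bin = NA`.
#' @export
learning_curves <- function(trials) {
  trials$bin <- ceiling(trials$trial_in_block / 4)
  exp_tr <- trials[trials$block_kind != "reference", ]
  key <- interaction(exp_tr$session, exp_tr$pair, exp_tr$bin, drop = TRUE)
  med <- tapply(exp_tr$signed_error, key, stats::median)
  info <- do.call(rbind, strsplit(names(med), "\\."))
  per <- data.frame(session = info[, 1], pair = info[, 2],
                    bin = as.integer(info[, 3]), median_error = as.numeric(med))
  agg <- stats::aggregate(median_error ~ pair + bin, data = per,
                          FUN = function(x) c(mean(x), stats::sd(x), length(x)))
  out <- data.frame(
    pair = agg$pair, bin = agg$bin,
    mean_error = agg$median_error[, 1],
    sd_error = agg$median_error[, 2],
    n_sessions = agg$median_error[, 3]
  )
  ref <- trials[trials$block_kind == "reference", ]
  if (nrow(ref) > 0) {
    med_ref <- tapply(ref$signed_error, ref$session, stats::median)
    out <- rbind(out, data.frame(
      pair = "reference", bin = NA_integer_,
      mean_error = mean(med_ref), sd_error = stats::sd(med_ref),
      n_sessions = length(med_ref)
    ))
  }
  out[order(out$pair, out$bin), ]
}

#' Model error differences by the timing of a step
#'
#' The model twin of the step-sorted tapping-error analysis: for each step
#' time relative to the tap, simulated trials are split by the size of the
#' step at that time and the mean difference in model-predicted error is
#' returned.
#'
#' @param sessions a list of data.frames from [simulate_drift_session()]
#'   run with `keep_steps = TRUE` (or a single such data.frame).
#' @param offsets_frames step times before the tap, in frames (offset `o`
#'   means the step into frame `tap_frame - o + 1`).
#' @param min_cell minimum trials per split cell; smaller cells give `NA`.
#' @return data.frame with `offset_frames`, `offset_ms`, `error_diff` (mm,
#'   large-step minus small-step trials) and `n`.
#' @export
step_error_curve <- function(sessions, offsets_frames = 1:48, min_cell = 20) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  errors <- unlist(lapply(sessions, function(s) s$error))
  taps <- unlist(lapply(sessions, function(s) s$tap_frame))
  steps <- do.call(c, lapply(sessions, function(s) attr(s, "steps")))
  if (is.null(steps)) stop("sessions must be simulated with keep_steps = TRUE",
                           call. = FALSE)
  # the step with index tap_frame - o lands (o - 1) frames before the tap
  out <- data.frame(offset_frames = offsets_frames,
                    offset_ms = (offsets_frames - 1) * FRAME_DT * 1000,
                    error_diff = NA_real_, n = NA_integer_)
  for (j in seq_along(offsets_frames)) {
    o <- offsets_frames[j]
    idx <- taps - o
    ok <- idx >= 1 & is.finite(errors)
    st <- vapply(which(ok), function(i) steps[[i]][idx[i]], numeric(1))
    med <- mean(range(st))
    hi <- st > med
    lo <- st < med
    if (sum(hi) >= min_cell && sum(lo) >= min_cell) {
      e <- errors[ok]
      out$error_diff[j] <- mean(e[hi]) - mean(e[lo])
      out$n[j] <- sum(ok)
    }
  }
  out
}
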