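#' Leaky-integrator velocity accumulation and delayed extrapolation
#'
#' The aiming model assumes that at time `t` the hand is guided towards the
#' target position seen one visuomotor delay earlier, extrapolated to the
#' anticipated tap time with a running estimate of the target's velocity.
#' The velocity estimate is a leaky integrator: after every displayed step a
#' fixed fraction `w` of the step's velocity replaces the previous estimate,
#'
#'   v_s = (1 - w) v_{s-1} + w v_step.
#'
#' With w = 0.02 per 120 Hz frame the estimate takes 35 frames (almost
#' 300 ms) to move halfway to a new constant velocity; the fast variant uses
#' w = 0.15.
#'
#' @name velocity-accumulation
NULL

#' Accumulator parameters
#'
#' @param w update weight per frame, in (0, 1].
#' @param delay_frames visuomotor delay in display frames (default 12, i.e.
#'   100 ms at 120 Hz).
#' @return a list of class `accumulator_params`.
#' @export
accumulator_params <- function(w = 0.02, delay_frames = DELAY_FRAMES) {
  if (w <= 0 || w > 1) stop("w must be in (0, 1]", call. = FALSE)
  if (delay_frames != round(delay_frames) || delay_frames < 0) {
    stop("delay_frames must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(w = w, delay_frames = as.integer(delay_frames),
         delay_s = delay_frames * FRAME_DT, frame_dt = FRAME_DT),
    class = "accumulator_params"
  )
}

#' Single leaky-integrator update
#'
#' @param v_prev previous velocity estimate (mm/s).
#' @param v_step velocity of the latest step (mm/s).
#' @param w update weight.
#' @return the updated estimate (mm/s).
#' @export
update_velocity <- function(v_prev, v_step, w) {
  (1 - w) * v_prev + w * v_step
}

#' Iterated accumulation over a sequence of step velocities
#'
#' Returns the estimate after each update (a linear recursive filter).
#'
#' @param v0 initial estimate (mm/s).
#' @param v_steps per-frame step velocities (mm/s).
#' @param w update weight.
#' @return numeric vector, `length(v_steps)` estimates.
#' @export
accumulate_velocity <- function(v0, v_steps, w) {
  if (length(v_steps) == 0) return(numeric(0))
  as.numeric(stats::filter(w * v_steps, 1 - w, method = "recursive", init = v0))
}

# estimate after exactly n updates, without materialising the series:
# v_n = (1-w)^n v0 + w * sum_k (1-w)^(n-k) v_k
velocity_after <- function(v0, v_steps, w, n) {
  if (n <= 0) return(v0)
  decay <- (1 - w)^(n - seq_len(n))
  (1 - w)^n * v0 + w * sum(decay * v_steps[seq_len(n)])
}

#' Extrapolated aim point
#'
#' `A = T_delayed + v_delayed * (t_tap - (t - delta))`: the target position a
#' delay ago, extrapolated with the delayed velocity estimate over the time
#' remaining until the anticipated tap plus the delay itself.
#'
#' @param T_delayed target position a delay before `t` (mm).
#' @param v_delayed velocity estimate at that moment (mm/s).
#' @param t current time (s).
#' @param t_tap anticipated tap time (s).
#' @param delta visuomotor delay (s).
#' @return the aim point (mm).
#' @export
aim_point <- function(T_delayed, v_delayed, t, t_tap, delta = DELAY_S) {
  stopifnot(t_tap >= t - delta)
  T_delayed + v_delayed * (t_tap - (t - delta))
}

#' Model-predicted tapping error
#'
#' Evaluating the aim point at the tap gives the predicted signed error
#' `A_tap - T_tap = T_{tap-delta} - T_tap + v_{tap-delta} * delta`
#' (positive = tap to the right of the target on screen).
#'
#' @param traj a [target_trajectory()].
#' @param tap_frame display frame of the tap (1-based).
#' @param v_delay velocity estimate one delay before the tap (mm/s).
#' @param delay_frames delay in frames.
#' @return predicted error in mm.
#' @export
predicted_tap_error <- function(traj, tap_frame, v_delay,
                                delay_frames = DELAY_FRAMES) {
  if (tap_frame > traj$n_frames) stop("tap_frame beyond trajectory", call. = FALSE)
  if (tap_frame - delay_frames < 1) {
    stop("tap earlier than one delay after trajectory onset", call. = FALSE)
  }
  traj$positions[tap_frame - delay_frames] - traj$positions[tap_frame] +
    v_delay * delay_frames * FRAME_DT
}

#' Run the accumulator over one trial
#'
#' Applies one update per displayed frame from trajectory onset through the
#' tap. The predicted error uses the estimate available one delay before the
#' tap; the estimate at the tap is returned for carry-over to the next trial.
#' If the tap occurs within one delay of onset the carried-over estimate is
#' used for the error (flagged).
#'
#' @param traj a [target_trajectory()].
#' @param tap_frame display frame of the tap.
#' @param params an [accumulator_params()].
#' @param initial_v estimate carried over from the previous trial (mm/s).
#' @param keep_series return the full per-frame estimate series?
#' @return list with `predicted_error`, `v_delay`, `final_v`, and optionally
#'   `v_series` (estimate after each of the `tap_frame - 1` observed steps).
#' @export
run_trial_accumulation <- function(traj, tap_frame, params, initial_v,
                                   keep_series = FALSE) {
  if (tap_frame > traj$n_frames) stop("tap_frame beyond trajectory", call. = FALSE)
  vs <- traj$step_velocities
  n_obs <- tap_frame - 1L # steps shown before the tap
  n_delay <- tap_frame - params$delay_frames - 1L # steps shown by tap - delay
  early_tap <- n_delay < 0L
  v_delay <- velocity_after(initial_v, vs, params$w, max(n_delay, 0L))
  final_v <- velocity_after(initial_v, vs, params$w, n_obs)
  err <- if (tap_frame - params$delay_frames >= 1) {
    predicted_tap_error(traj, tap_frame, v_delay, params$delay_frames)
  } else {
    NA_real_
  }
  out <- list(predicted_error = err, v_delay = v_delay, final_v = final_v,
              early_tap = early_tap)
  if (keep_series) out$v_series <- accumulate_velocity(initial_v, vs[seq_len(n_obs)], params$w)
  out
}
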