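#' Trial-to-trial error-correction learning with forgetting
#'
#' Two corrections adjust the aim point between trials: a spatial offset
#' `C_s` (mm) and a temporal offset `C_t` (s) that lengthens or shortens the
#' extrapolation horizon. After every tap each correction is pulled back
#' towards zero (retention 0.95) and adjusted against the trial's error:
#'
#'   C_s' = 0.95 C_s - 0.25 (A_tap - T_tap)
#'   C_t' = 0.95 C_t - 0.15 (t_passed - t_tap)
#'
#' where `t_passed` is when the target passed (or would have passed) the
#' tapped position. Both corrections start at zero at the beginning of each
#' session. The forgetting term is what keeps the pair stable when both
#' corrections can compensate for the same error.
#'
#' @name error-learning
NULL

#' Learning parameters
#'
#' @param retention per-trial retention of each correction (0.95).
#' @param spatial_rate fraction of the spatial error corrected (0.25).
#' @param temporal_rate fraction of the timing error corrected (0.15).
#' @return a list of class `learning_params`.
#' @export
learning_params <- function(retention = 0.95, spatial_rate = 0.25,
                            temporal_rate = 0.15) {
  stopifnot(retention > 0, retention <= 1,
            spatial_rate > 0, spatial_rate <= 1,
            temporal_rate > 0, temporal_rate <= 1)
  structure(list(retention = retention, spatial_rate = spatial_rate,
                 temporal_rate = temporal_rate),
            class = "learning_params")
}

#' Correction state
#'
#' @param C_s spatial correction (mm).
#' @param C_t temporal correction (s).
#' @return a list of class `correction_state`.
#' @export
correction_state <- function(C_s = 0, C_t = 0) {
  stopifnot(is.finite(C_s), is.finite(C_t))
  structure(list(C_s = C_s, C_t = C_t), class = "correction_state")
}

#' Aim point with learned corrections
#'
#' Extends the extrapolation horizon by `C_t` and offsets the result by
#' `C_s`; with a zero state this reduces to [aim_point()].
#'
#' @inheritParams aim_point
#' @param state a [correction_state()].
#' @return the corrected aim point (mm).
#' @export
corrected_aim_point <- function(T_delayed, v_delayed, t, t_tap,
                                delta = DELAY_S, state = correction_state()) {
  T_delayed + v_delayed * (t_tap + state$C_t - (t - delta)) + state$C_s
}

#' Update the spatial correction after a tap
#'
#' @param state a [correction_state()].
#' @param tap_error signed lateral error `A_tap - T_tap` (mm).
#' @param params a [learning_params()].
#' @return the new state (`C_t` unchanged).
#' @export
update_spatial <- function(state, tap_error, params = learning_params()) {
  correction_state(
    C_s = params$retention * state$C_s - params$spatial_rate * tap_error,
    C_t = state$C_t
  )
}

#' Update the temporal correction after a tap
#'
#' @param state a [correction_state()].
#' @param timing_error `t_passed - t_tap` (s).
#' @param params a [learning_params()].
#' @return the new state (`C_s` unchanged).
#' @export
update_temporal <- function(state, timing_error, params = learning_params()) {
  correction_state(
    C_s = state$C_s,
    C_t = params$retention * state$C_t - params$temporal_rate * timing_error
  )
}

#' When the target passes the tapped position
#'
#' Inverts the target's kinematics at the tapped position. For trajectories
#' with a closed-form kinematic description (constant acceleration) the
#' quadratic is solved directly, extrapolating beyond the displayed frames if
#' needed; for step trajectories the piecewise-linear path is searched for a
#' crossing and extrapolated with the mean step velocity beyond its end. If a
#' decelerating target stops short of the tapped position the crossing is
#' undefined; the signed time of closest approach is returned with
#' `undefined_crossing = TRUE`.
#'
#' @param traj a [target_trajectory()].
#' @param tapped_position lateral position of the tap (mm).
#' @param t_tap tap time (s).
#' @return list with `timing_error` (`t_passed - t_tap`, s), `t_passed`, and
#'   flag `undefined_crossing`.
#' @export
timing_error <- function(traj, tapped_position, t_tap) {
  kin <- traj$kinematics
  if (!is.null(kin)) {
    # x(t) = x0 + b t + c t^2 ; solve for x = tapped_position
    d <- tapped_position - kin$x0
    if (abs(kin$c) < 1e-12) {
      if (abs(kin$b) < 1e-9) {
        return(list(timing_error = NA_real_, t_passed = NA_real_,
                    undefined_crossing = TRUE))
      }
      t_passed <- d / kin$b
      return(list(timing_error = t_passed - t_tap, t_passed = t_passed,
                  undefined_crossing = FALSE))
    }
    disc <- kin$b^2 + 4 * kin$c * d
    # velocity reaches zero at t_stop (only relevant when decelerating)
    t_stop <- if (kin$accel_along < 0) kin$v0 / abs(kin$accel_along) else Inf
    if (disc < 0) {
      # target never reaches the tapped position: closest approach at t_stop
      return(list(timing_error = t_stop - t_tap, t_passed = t_stop,
                  undefined_crossing = TRUE))
    }
    roots <- (-kin$b + c(-1, 1) * sqrt(disc)) / (2 * kin$c)
    valid <- roots[roots >= 0 & roots <= t_stop + 1e-12]
    if (length(valid) == 0) {
      return(list(timing_error = t_stop - t_tap, t_passed = t_stop,
                  undefined_crossing = TRUE))
    }
    t_passed <- min(valid)
    return(list(timing_error = t_passed - t_tap, t_passed = t_passed,
                undefined_crossing = FALSE))
  }
  # step trajectory: search the piecewise-linear path
  pos <- traj$positions
  tms <- traj$times
  rel <- pos - tapped_position
  cross <- which(rel[-1] * rel[-length(rel)] <= 0)
  if (length(cross) > 0) {
    i <- cross[1]
    if (rel[i] == 0) {
      t_passed <- tms[i]
    } else {
      frac <- abs(rel[i]) / (abs(rel[i]) + abs(rel[i + 1]))
      t_passed <- tms[i] + frac * FRAME_DT
    }
    return(list(timing_error = t_passed - t_tap, t_passed = t_passed,
                undefined_crossing = FALSE))
  }
  v_mean <- mean(traj$step_velocities)
  if (abs(v_mean) < 1e-9) {
    return(list(timing_error = NA_real_, t_passed = NA_real_,
                undefined_crossing = TRUE))
  }
  t_passed <- tms[length(tms)] + (tapped_position - pos[length(pos)]) / v_mean
  undefined <- t_passed < tms[length(tms)]
  list(timing_error = t_passed - t_tap, t_passed = t_passed,
       undefined_crossing = undefined)
}
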