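#' Step-triggered response analysis
#'
#' The kinematic analysis pipeline: lightly smoothed position and velocity
#' estimates from a 9-point second-order Savitzky-Golay fit, on-line style
#' tap detection from the impact deceleration, exclusion rules, tap-aligned
#' step-sorted trial splitting, response curves (the difference in lateral
#' finger velocity between the two sorted trial sets as a function of time
#' from the step), peak gains, and step-sorted tapping-error differences.
#'
#' @name response-analysis
NULL

#' Savitzky-Golay position and velocity
#'
#' Fits a second-order polynomial to the 9 samples around each sample (8 ms
#' on either side at 500 Hz) and evaluates the fit and its derivative at the
#' sample. End samples use the off-centre rows of the full 9-point projection
#' matrix, which remain exact for quadratic inputs. Gaps (`NA`) of at most
#' `max_gap_ms` are linearly interpolated first; longer gaps are an error
#' (use [exclude_trials()] upstream).
#'
#' @param x positions (mm), sampled at `1/dt` Hz.
#' @param dt sample interval (s).
#' @param max_gap_ms longest interpolatable gap (ms).
#' @return list with `position` and `velocity` (mm, mm/s).
#' @export
savgol_kinematics <- function(x, dt = SAMPLE_DT, max_gap_ms = 20) {
  if (length(x) < 9) stop("need at least 9 samples", call. = FALSE)
  if (anyNA(x)) {
    if (all(is.na(x))) stop("all samples missing", call. = FALSE)
    gap_len <- max(rle(is.na(x))$lengths[rle(is.na(x))$values])
    if (gap_len * dt * 1000 > max_gap_ms) {
      stop("gap longer than ", max_gap_ms, " ms", call. = FALSE)
    }
    x <- stats::approx(seq_along(x), x, xout = seq_along(x), rule = 2)$y
  }
  list(
    position = as.numeric(signal::sgolayfilt(x, p = 2, n = 9, m = 0)),
    velocity = as.numeric(signal::sgolayfilt(x, p = 2, n = 9, m = 1, ts = dt))
  )
}

#' Detect the tap from the finger's approach to the screen
#'
#' Replicates the on-line criterion: acceleration away from the screen,
#' computed as the difference between the two displacements within three
#' consecutive samples, exceeding 50 m/s^2 while the finger is less than
#' 5 mm from the screen and was moving towards it. If no sample satisfies
#' the criterion but the finger does come within 5 mm of the screen, the
#' minimum finger-screen distance is used (gentle tap fallback); if it never
#' comes within 5 mm there was no tap.
#'
#' @param trial a data.frame with `time` and `z` (finger-screen distance, mm).
#' @param accel_threshold impact deceleration threshold (mm/s^2).
#' @param z_max maximum distance from the screen at the tap (mm).
#' @return list with `tap_index`, `tap_time`, `mode`
#'   (`"acceleration"` or `"z_minimum"`).
#' @export
detect_tap <- function(trial, accel_threshold = 5e4, z_max = 5) {
  z <- trial$z
  n <- length(z)
  if (min(z) >= z_max) {
    stop("no tap: finger never within ", z_max, " mm of the screen",
         call. = FALSE)
  }
  dt <- stats::median(diff(trial$time))
  i <- 2:(n - 1)
  accel <- (z[i + 1] - 2 * z[i] + z[i - 1]) / dt^2
  towards <- z[i] - z[i - 1] < 0
  hit <- which(accel > accel_threshold & z[i] < z_max & towards)
  if (length(hit) > 0) {
    idx <- hit[1] + 1L
    mode <- "acceleration"
  } else {
    idx <- which.min(z)
    mode <- "z_minimum"
  }
  list(tap_index = idx, tap_time = trial$time[idx], mode = mode)
}

#' Apply the trial exclusion rules
#'
#' Excludes trials tapped after the target would have disappeared (tap later
#' than `max_tap_time` after target onset) and trials whose finger position
#' is missing for longer than `max_gap_ms`; shorter gaps are linearly
#' interpolated in place.
#'
#' @param trials list of `finger_trial` data.frames (may contain `NA` runs in
#'   `x`, `y`, `z`).
#' @param max_tap_time latest allowed tap time (s).
#' @param max_gap_ms longest interpolatable gap (ms).
#' @return list with `trials` (retained, gaps interpolated) and `report`
#'   (counts per rule).
#' @export
exclude_trials <- function(trials, max_tap_time = 0.7, max_gap_ms = 20) {
  keep <- logical(length(trials))
  reason <- character(length(trials))
  cleaned <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (attr(tr, "tap_time") > max_tap_time) {
      reason[i] <- "late_tap"
      next
    }
    gap_ok <- TRUE
    for (col in c("x", "y", "z")) {
      v <- tr[[col]]
      if (anyNA(v)) {
        r <- rle(is.na(v))
        if (max(r$lengths[r$values]) * SAMPLE_DT * 1000 > max_gap_ms) {
          gap_ok <- FALSE
          break
        }
        tr[[col]] <- stats::approx(seq_along(v), v, xout = seq_along(v),
                                   rule = 2)$y
      }
    }
    if (!gap_ok) {
      reason[i] <- "gap"
      next
    }
    keep[i] <- TRUE
    cleaned[[i]] <- tr
  }
  list(
    trials = cleaned[keep],
    report = c(retained = sum(keep),
               late_tap = sum(reason == "late_tap"),
               gap = sum(reason == "gap"))
  )
}

# step index queried at a given offset: the step with index tap_frame - o
# lands (o - 1) frames before the tap
step_at_offset <- function(trial, offset_frames) {
  traj <- attr(trial, "target")
  idx <- attr(trial, "tap_frame") - offset_frames
  if (idx < 1) return(NA_real_)
  traj$steps[idx]
}

#' Sort trials by the step at a given time before the tap
#'
#' Partitions tap-aligned trials by whether the step landing
#' `offset_frames - 1` frames before the tap was above or below the midpoint
#' of the step distribution (direction for a random walk, size for a
#' drifting walk). Steps at all other times are balanced across the two sets
#' in expectation.
#'
#' @param trials list of `finger_trial` objects.
#' @param offset_frames offset of the queried step (1 = the step into the
#'   tap frame; 13 = the step 100 ms before the tap).
#' @return list with index vectors `high` and `low` and the queried
#'   `step_values`.
#' @export
split_by_step <- function(trials, offset_frames) {
  vals <- vapply(trials, step_at_offset, numeric(1),
                 offset_frames = offset_frames)
  mid <- mean(range(vals, na.rm = TRUE))
  list(high = which(!is.na(vals) & vals > mid),
       low = which(!is.na(vals) & vals < mid),
       step_values = vals)
}

# smooth every trial's lateral coordinate once
smooth_trials <- function(trials) {
  lapply(trials, function(tr) {
    k <- savgol_kinematics(tr$x)
    tr$x_s <- k$position
    tr$vx <- k$velocity
    tr
  })
}

#' Tap-aligned response curves
#'
#' For each queried step time, sorts the trials with [split_by_step()] and
#' returns the mean difference in smoothed lateral finger position and
#' velocity between the two sets, as a function of the time from the step.
#' The velocity difference is the "response".
#'
#' @param trials list of `finger_trial` objects.
#' @param offsets_frames step offsets before the tap (frames).
#' @param window_s time window around the step (s).
#' @param min_cell minimum trials per set; smaller cells are skipped.
#' @return data.frame with `offset_frames`, `step_before_tap_ms`,
#'   `t_from_step`, `dpos`, `dvel`, `n_high`, `n_low`.
#' @export
response_curves <- function(trials, offsets_frames,
                            window_s = c(-0.1, 0.35), min_cell = 10) {
  trials <- smooth_trials(trials)
  grid <- seq(window_s[1], window_s[2], by = SAMPLE_DT)
  curves <- list()
  for (o in offsets_frames) {
    sp <- split_by_step(trials, o)
    if (length(sp$high) < min_cell || length(sp$low) < min_cell) next
    set_mean <- function(idx) {
      acc_p <- matrix(NA_real_, length(idx), length(grid))
      acc_v <- matrix(NA_real_, length(idx), length(grid))
      for (r in seq_along(idx)) {
        tr <- trials[[idx[r]]]
        t_step <- (attr(tr, "tap_frame") - o) * FRAME_DT
        tt <- tr$time - t_step
        main <- seq_len(attr(tr, "tap_index"))
        acc_p[r, ] <- stats::approx(tt[main], tr$x_s[main], xout = grid)$y
        acc_v[r, ] <- stats::approx(tt[main], tr$vx[main], xout = grid)$y
      }
      list(p = colMeans(acc_p, na.rm = TRUE), v = colMeans(acc_v, na.rm = TRUE))
    }
    hi <- set_mean(sp$high)
    lo <- set_mean(sp$low)
    curves[[length(curves) + 1L]] <- data.frame(
      offset_frames = o,
      step_before_tap_ms = (o - 1) * FRAME_DT * 1000,
      t_from_step = grid,
      dpos = hi$p - lo$p,
      dvel = hi$v - lo$v,
      n_high = length(sp$high),
      n_low = length(sp$low)
    )
  }
  do.call(rbind, curves)
}

#' Peak response gain per step time
#'
#' Divides each response curve by the step-size difference between the two
#' sorted sets and takes the maximum over the time from the step.
#'
#' @param curves output of [response_curves()].
#' @param step_delta difference in step size between the sets (mm); for a
#'   random walk with +/-s steps this is `2 s`.
#' @param t_range time window in which to search for the peak (s).
#' @return data.frame with `offset_frames`, `step_before_tap_ms`,
#'   `peak_response` (mm/s) and `peak_gain` (1/s).
#' @export
peak_gain <- function(curves, step_delta, t_range = c(0.05, 0.35)) {
  out <- lapply(split(curves, curves$offset_frames), function(cv) {
    sel <- cv$t_from_step >= t_range[1] & cv$t_from_step <= t_range[2] &
      is.finite(cv$dvel)
    pk <- if (any(sel)) max(cv$dvel[sel]) else NA_real_
    data.frame(offset_frames = cv$offset_frames[1],
               step_before_tap_ms = cv$step_before_tap_ms[1],
               peak_response = pk, peak_gain = pk / step_delta)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$offset_frames), ]
}

# target position at an arbitrary time, linearly interpolated within the
# step in question (extrapolated with the last step's velocity beyond the end)
target_position_at <- function(traj, t) {
  f <- t / FRAME_DT + 1
  n <- traj$n_frames
  if (f >= n) {
    return(traj$positions[n] + (f - n) * traj$steps[n - 1])
  }
  i <- floor(f)
  traj$positions[i] + (f - i) * traj$steps[max(i, 1)]
}

#' Tapping error of one analysed trial
#'
#' Signed lateral difference between the tap position and the target
#' position at the tap time (target position linearly interpolated within
#' the step in question).
#'
#' @param trial a `finger_trial`.
#' @param tap a tap event from [detect_tap()]; detected if missing.
#' @return error in mm (positive = tap right of the target).
#' @export
tapping_error <- function(trial, tap = NULL) {
  if (is.null(tap)) tap <- detect_tap(trial)
  traj <- attr(trial, "target")
  trial$x[tap$tap_index] - target_position_at(traj, tap$tap_time)
}

#' Step-sorted tapping-error differences
#'
#' For each queried step time, the mean difference in signed tapping error
#' between the two step-sorted trial sets. Fully corrected steps give
#' differences near zero; steps within the visuomotor latency of the tap are
#' not corrected at all, so the difference approaches minus twice the step
#' size; slightly earlier steps can overshoot (positive differences) when
#' the response model is underdamped.
#'
#' @param trials list of `finger_trial` objects.
#' @param offsets_frames step offsets before the tap (frames).
#' @param min_cell minimum trials per set.
#' @return data.frame with `offset_frames`, `step_before_tap_ms`,
#'   `error_diff` (mm) and set sizes.
#' @export
error_split <- function(trials, offsets_frames, min_cell = 10) {
  errs <- vapply(trials, tapping_error, numeric(1))
  out <- data.frame(offset_frames = offsets_frames,
                    step_before_tap_ms = (offsets_frames - 1) * FRAME_DT * 1000,
                    error_diff = NA_real_, n_high = NA_integer_,
                    n_low = NA_integer_)
  for (j in seq_along(offsets_frames)) {
    sp <- split_by_step(trials, offsets_frames[j])
    if (length(sp$high) < min_cell || length(sp$low) < min_cell) next
    out$error_diff[j] <- mean(errs[sp$high]) - mean(errs[sp$low])
    out$n_high[j] <- length(sp$high)
    out$n_low[j] <- length(sp$low)
  }
  out
}

#' Estimate the response latency from a response curve
#'
#' Fits a line to the rising phase of the velocity-difference curve (between
#' two fractions of its peak) and extrapolates back to the zero crossing.
#'
#' @param curve one offset's rows from [response_curves()].
#' @param frac fractions of the peak bounding the rising phase.
#' @return estimated latency in seconds.
#' @export
response_latency <- function(curve, frac = c(0.25, 0.75)) {
  ok <- is.finite(curve$dvel) & curve$t_from_step >= 0
  tt <- curve$t_from_step[ok]
  v <- curve$dvel[ok]
  pk_i <- which.max(v)
  pk <- v[pk_i]
  rising <- which(tt <= tt[pk_i] & v >= frac[1] * pk & v <= frac[2] * pk)
  if (length(rising) < 2) return(NA_real_)
  fit <- stats::lm(v[rising] ~ tt[rising])
  -stats::coef(fit)[[1]] / stats::coef(fit)[[2]]
}
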