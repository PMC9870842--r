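#' Response models and synthetic finger trajectories
#'
#' Two simple models describe how the finger responds to a small target
#' displacement D when T milliseconds remain for the response (the response
#' starts one visuomotor latency, 100 ms, after the displacement):
#' a minimum-jerk correction that traverses D as smoothly as possible in
#' exactly T, and a mass-spring-damper pulled by the displacement with fixed
#' damping and a stiffness that grows as less time remains,
#' `k = 3800 - 16 T` (T in ms), making late responses more vigorous and
#' underdamped (overshooting) for T below about 150 ms.
#'
#' @name finger-synthesis
NULL

#' Minimum-jerk correction velocity
#'
#' `xdot = 30 D t^2 (1 - t)^2 / T` with `t` the elapsed fraction of the
#' available time; the integral over the response equals D exactly.
#'
#' @param D displacement to traverse (mm).
#' @param T_s available time (s).
#' @param t_frac elapsed time as a fraction of `T_s` (in `[0, 1]`).
#' @return velocity in mm/s.
#' @export
min_jerk_velocity <- function(D, T_s, t_frac) {
  if (T_s <= 0) stop("available time must be positive", call. = FALSE)
  stopifnot(all(t_frac >= 0 & t_frac <= 1))
  30 * D * t_frac^2 * (1 - t_frac)^2 / T_s
}

#' Minimum-jerk point-to-point position profile
#'
#' @param amplitude total displacement.
#' @param t_frac elapsed fraction of the movement.
#' @return position along the movement.
#' @export
min_jerk_position <- function(amplitude, t_frac) {
  s <- pmin(pmax(t_frac, 0), 1)
  amplitude * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

#' Mass-spring-damper stiffness for a given available time
#'
#' @param T_ms available response time (ms).
#' @param k_intercept,k_slope stiffness law parameters (s^-2 and s^-2 per ms).
#' @return stiffness in s^-2.
#' @export
msd_stiffness <- function(T_ms, k_intercept = 3800, k_slope = 16) {
  k <- k_intercept - k_slope * T_ms
  if (any(k <= 0)) stop("stiffness must be positive over the supported T range",
                        call. = FALSE)
  k
}

#' Available time at which the damping regime changes
#'
#' Solves `b^2 = 4 k(T)`; the system is underdamped (overshoots) for shorter
#' available times.
#'
#' @param b damping rate (s^-1).
#' @inheritParams msd_stiffness
#' @return the critical available time in ms.
#' @export
msd_critical_T <- function(b = 75, k_intercept = 3800, k_slope = 16) {
  (k_intercept - b^2 / 4) / k_slope
}

#' Closed-form mass-spring-damper response to a displacement
#'
#' Solves `xddot + b xdot + k x = 0` with `x(0) = D` (the remaining
#' discrepancy) and `xdot(0) = 0`; the reported response velocity is
#' `-xdot(t)`, i.e. movement towards the displaced target. The over-, under-
#' and critically damped branches are handled in closed form.
#'
#' @param D displacement (mm).
#' @param T_ms available response time (ms), sets the stiffness.
#' @param times evaluation times since response onset (s).
#' @param b damping rate (s^-1).
#' @inheritParams msd_stiffness
#' @return list with `times`, `x` (remaining discrepancy, mm), `velocity`
#'   (response velocity `-xdot`, mm/s), `k`, and `regime`.
#' @export
msd_response <- function(D, T_ms, times, b = 75,
                         k_intercept = 3800, k_slope = 16) {
  k <- msd_stiffness(T_ms, k_intercept, k_slope)
  g <- b / 2
  disc <- b^2 - 4 * k
  if (abs(disc) < 1e-9) {
    regime <- "critical"
    x <- D * exp(-g * times) * (1 + g * times)
    xdot <- -D * g^2 * times * exp(-g * times)
  } else if (disc > 0) {
    regime <- "overdamped"
    s <- sqrt(disc) / 2
    l1 <- -g + s
    l2 <- -g - s
    x <- D * (l2 * exp(l1 * times) - l1 * exp(l2 * times)) / (l2 - l1)
    xdot <- D * l1 * l2 * (exp(l1 * times) - exp(l2 * times)) / (l2 - l1)
  } else {
    regime <- "underdamped"
    w <- sqrt(4 * k - b^2) / 2
    x <- D * exp(-g * times) * (cos(w * times) + (g / w) * sin(w * times))
    xdot <- -D * (k / w) * exp(-g * times) * sin(w * times)
  }
  list(times = times, x = x, velocity = -xdot, k = k, regime = regime)
}

#' Synthesize a 500 Hz finger trajectory for one trial
#'
#' The lateral finger velocity is the superposition of the chosen model's
#' responses to every target step's deviation from the expected step (the
#' jitter scheme's mean displacement per frame; each response starting one
#' latency after its step, with its own remaining time), on top of a
#' minimum-jerk transport profile towards the target's expected tap
#' position. The transport is deliberately independent of the realized
#' jitter so that no step's displacement leaks into the movement before the
#' response latency. The vertical component is a stereotyped reach whose
#' height returns to the screen at the tap with an impact deceleration well
#' above the detection threshold; a few post-impact samples are appended so
#' that on-line tap detection can see the impact.
#'
#' @param traj a [target_trajectory()] covering at least the tap frame.
#' @param tap_frame display frame of the tap.
#' @param movement_time movement duration (s); the reach starts at
#'   `tap_time - movement_time`.
#' @param model `"msd"` or `"min_jerk"`.
#' @param latency visuomotor latency (s).
#' @param noise_sd white positional noise SD per sample (mm).
#' @param reach_amplitude reach extent along the screen (mm).
#' @param z_peak maximum finger-screen distance during the reach (mm).
#' @param expected_step expected target displacement per frame (mm); 0 for
#'   a pure random walk, the scheme's mean step for a drifting walk.
#' @param msd_T_cap_ms cap on the available time used to set the stiffness.
#'   The stiffness law is parameterised for responses with at most about
#'   200 ms available (steps up to 300 ms before the tap); steps earlier
#'   than that respond with the stiffness at the cap, under which they have
#'   ample time to settle before the tap.
#' @param seed optional seed for the noise.
#' @return a data.frame (`time`, `x`, `y`, `z`) of class `finger_trial` with
#'   attributes `target` (the trajectory), `tap_index`, `tap_time`,
#'   `tap_frame`, `model`.
#' @export
synthesize_trial <- function(traj, tap_frame, movement_time = 0.29,
                             model = c("msd", "min_jerk"),
                             latency = DELAY_S, noise_sd = 0.5,
                             reach_amplitude = 250, z_peak = 40,
                             expected_step = 0,
                             msd_T_cap_ms = 200, seed = NULL) {
  model <- match.arg(model)
  if (tap_frame > traj$n_frames) stop("tap_frame beyond trajectory", call. = FALSE)
  tap_time <- (tap_frame - 1L) * FRAME_DT
  rt <- tap_time - movement_time
  if (rt < 0) stop("movement_time longer than the trial", call. = FALSE)
  n_main <- floor(tap_time / SAMPLE_DT) + 1L
  n_post <- 10L
  tt <- (seq_len(n_main + n_post) - 1L) * SAMPLE_DT
  tap_index <- n_main
  moving <- tt >= rt & tt <= tap_time
  s <- rep(0, length(tt))
  s[moving] <- (tt[moving] - rt) / movement_time
  s[tt > tap_time] <- 1

  y <- min_jerk_position(reach_amplitude, s)
  z <- z_peak * sin(pi * s)
  z[tt > tap_time] <- 0

  # transport starts at the starting point (lateral 0) and heads for the
  # target's expected position at the tap; deviations from it are what the
  # per-step responses correct
  end_x <- traj$positions[1] + expected_step * (tap_frame - 1L)
  x_base <- min_jerk_position(end_x, s)

  v_resp <- rep(0, length(tt))
  devs <- traj$steps[seq_len(tap_frame - 1L)] - expected_step
  for (j in which(abs(devs) > 1e-12)) {
    onset <- j * FRAME_DT + latency
    T_avail <- tap_time - onset
    if (T_avail <= SAMPLE_DT) next
    sel <- tt >= onset & tt <= tap_time
    rel <- tt[sel] - onset
    if (model == "min_jerk") {
      v_resp[sel] <- v_resp[sel] +
        min_jerk_velocity(devs[j], T_avail, rel / T_avail)
    } else {
      T_ms <- min(T_avail * 1000, msd_T_cap_ms)
      v_resp[sel] <- v_resp[sel] + msd_response(devs[j], T_ms, rel)$velocity
    }
  }
  x <- x_base + cumsum(v_resp) * SAMPLE_DT
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length(tt), 0, noise_sd))
  }
  out <- data.frame(time = tt, x = x, y = y, z = z)
  structure(out,
            class = c("finger_trial", "data.frame"),
            target = traj, tap_index = tap_index, tap_time = tap_time,
            tap_frame = tap_frame, model = model)
}

#' Synthesize a batch of jittering-target trials
#'
#' Convenience generator for end-to-end analysis tests: draws a tap frame and
#' movement time per trial, generates a jittering target (random walk by
#' default, or a drifting walk under a variability scheme) and synthesizes
#' the finger trajectory.
#'
#' @param n_trials number of trials.
#' @param scheme `NULL` for the +/-5/3 mm random walk, or a
#'   [variability_scheme()].
#' @param model response model passed to [synthesize_trial()].
#' @param tap_model a [tap_time_model()].
#' @param noise_sd positional noise SD (mm).
#' @param seed master seed.
#' @return a list of `finger_trial` objects.
#' @export
synthesize_trials <- function(n_trials, scheme = NULL,
                              model = c("msd", "min_jerk"),
                              tap_model = tap_time_preset(1),
                              noise_sd = 0.5, seed = NULL) {
  model <- match.arg(model)
  seed <- if (is.null(seed)) sample.int(2^31 - 1, 1) else seed
  lapply(seq_len(n_trials), function(i) {
    ts <- derive_seed(seed, i)
    set.seed(ts)
    tap <- sample_tap_frame(1, tap_model)
    mt <- min(stats::rnorm(1, tap_model$movement_ms[1], tap_model$movement_ms[2]),
              1000 * (tap - 1) / FRAME_HZ - 30) / 1000
    mt <- max(mt, 0.15)
    if (is.null(scheme)) {
      traj <- make_random_walk(tap)
      exp_step <- 0
    } else {
      traj <- make_drifting_walk(tap, scheme$step_options, scheme$probabilities)
      exp_step <- sum(scheme$step_options * scheme$probabilities)
    }
    synthesize_trial(traj, tap, movement_time = mt, model = model,
                     noise_sd = noise_sd, expected_step = exp_step,
                     seed = derive_seed(ts, 1))
  })
}
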