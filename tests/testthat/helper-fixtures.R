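# small generators used across test files

# a constant-velocity trajectory (u mm/s) of n frames
const_velocity_traj <- function(u, n_frames = 72L, start_pos = 0) {
  target_trajectory(rep(u / 120, n_frames - 1L), start_pos)
}

# memoised batch of MSD-synthesized jittering-target trials (shared between
# the pipeline tests and the acceptance checks to keep the suite fast)
.batch_cache <- new.env(parent = emptyenv())
get_msd_batch <- function(n = 1500, seed = 500) {
  key <- sprintf("b_%d_%d", n, seed)
  if (is.null(.batch_cache[[key]])) {
    .batch_cache[[key]] <- synthesize_trials(n, model = "msd", seed = seed)
  }
  .batch_cache[[key]]
}

# numeric ODE oracle for the mass-spring-damper (requires deSolve)
msd_ode_oracle <- function(D, T_ms, times, b = 75) {
  k <- 3800 - 16 * T_ms
  deriv <- function(t, y, p) list(c(y[2], -b * y[2] - k * y[1]))
  out <- deSolve::ode(y = c(x = D, v = 0), times = times, func = deriv,
                      parms = NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-10)
  list(x = out[, "x"], velocity = -out[, "v"])
}
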