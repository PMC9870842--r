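#' Display and model constants
#'
#' The target display runs at 120 Hz (one lateral step every 8.3 ms), the
#' finger is sampled at 500 Hz, and visual information acts on the hand with
#' a visuomotor delay of about 100 ms, i.e. exactly 12 display frames.
#' Positions are in mm with the screen centre as lateral origin and rightward
#' positive; times are in seconds internally.
#'
#' @name tapsim-constants
#' @keywords internal
NULL

FRAME_HZ <- 120
FRAME_DT <- 1 / 120
SAMPLE_HZ <- 500
SAMPLE_DT <- 1 / 500
DELAY_S <- 0.1
DELAY_FRAMES <- 12L
SCREEN_HALF_MM <- 625 # 1.25 m wide screen

#' Per-frame step length for a lateral speed
#'
#' @param speed_cm_s speed in cm/s.
#' @return mm moved per 120 Hz frame.
#' @export
step_from_speed <- function(speed_cm_s) speed_cm_s * 10 / FRAME_HZ

#' Derive a reproducible per-trial seed from a session seed
#'
#' A splitmix-style integer hash so that any single trial of a seeded session
#' can be regenerated in isolation. The result is always in `[0, 2^31)`.
#'
#' @param seed integer session seed.
#' @param index trial index (1-based).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index) {
  x <- (as.double(seed) * 48271 + as.double(index) * 104729) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
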