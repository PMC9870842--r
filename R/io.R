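#' Trial-record files
#'
#' A batch of trials is exchanged as three plain-text files in one
#' directory: `trials.csv` (500 Hz finger samples), `targets.csv` (the 120 Hz
#' target step log) and `meta.json` (schema version, per-trial tap
#' annotations, seeds). Every `trial_id` in `trials.csv` must appear in both
#' other files.
#'
#' @name trial-io
NULL

TRIAL_SCHEMA_VERSION <- "1.0"

#' Write a batch of synthesized trials
#'
#' @param trials list of `finger_trial` objects.
#' @param dir output directory (created if needed).
#' @param seed optional seed recorded in the metadata.
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  finger <- do.call(rbind, lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(trial_id = i, time_s = tr$time, finger_x_mm = tr$x,
               finger_y_mm = tr$y, finger_z_mm = tr$z)
  }))
  targets <- do.call(rbind, lapply(seq_along(trials), function(i) {
    traj <- attr(trials[[i]], "target")
    data.frame(trial_id = i, frame_index = seq_len(traj$n_frames),
               time_s = traj$times, target_x_mm = traj$positions,
               step_mm = c(NA, traj$steps))
  }))
  meta <- list(
    schema_version = TRIAL_SCHEMA_VERSION,
    seed = seed,
    n_trials = length(trials),
    trials = lapply(seq_along(trials), function(i) {
      list(trial_id = i,
           tap_time = attr(trials[[i]], "tap_time"),
           tap_frame = attr(trials[[i]], "tap_frame"),
           model = attr(trials[[i]], "model"))
    })
  )
  utils::write.csv(finger, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(targets, file.path(dir, "targets.csv"), row.names = FALSE)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a batch of trials
#'
#' Validates the schema version, the required columns and that no trial is
#' orphaned across the three files, then rebuilds the `finger_trial`
#' objects.
#'
#' @param dir directory written by [write_trials()].
#' @return list of `finger_trial` objects.
#' @export
read_trials <- function(dir) {
  paths <- file.path(dir, c("trials.csv", "targets.csv", "meta.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing file(s): ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  finger <- utils::read.csv(paths[1])
  targets <- utils::read.csv(paths[2])
  meta <- jsonlite::read_json(paths[3])
  if (!identical(meta$schema_version, TRIAL_SCHEMA_VERSION)) {
    stop("unsupported schema version: ", meta$schema_version, call. = FALSE)
  }
  need_f <- c("trial_id", "time_s", "finger_x_mm", "finger_y_mm", "finger_z_mm")
  need_t <- c("trial_id", "frame_index", "time_s", "target_x_mm", "step_mm")
  if (!all(need_f %in% names(finger))) stop("trials.csv missing columns", call. = FALSE)
  if (!all(need_t %in% names(targets))) stop("targets.csv missing columns", call. = FALSE)
  ids_f <- sort(unique(finger$trial_id))
  ids_t <- sort(unique(targets$trial_id))
  ids_m <- sort(vapply(meta$trials, function(m) as.integer(m$trial_id), 0L))
  orphan <- union(setdiff(ids_f, ids_t), setdiff(ids_f, ids_m))
  if (length(orphan) > 0 || !identical(ids_f, ids_t) || !identical(ids_f, ids_m)) {
    bad <- unique(c(orphan, setdiff(ids_t, ids_f), setdiff(ids_m, ids_f)))
    stop("orphan trial_id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  lapply(meta$trials, function(m) {
    id <- as.integer(m$trial_id)
    f <- finger[finger$trial_id == id, ]
    tg <- targets[targets$trial_id == id, ]
    tg <- tg[order(tg$frame_index), ]
    traj <- target_trajectory(tg$step_mm[-1], start_pos = tg$target_x_mm[1])
    out <- data.frame(time = f$time_s, x = f$finger_x_mm,
                      y = f$finger_y_mm, z = f$finger_z_mm)
    tap_time <- as.numeric(m$tap_time)
    structure(out, class = c("finger_trial", "data.frame"),
              target = traj,
              tap_index = which.min(abs(out$time - tap_time)),
              tap_time = tap_time,
              tap_frame = as.integer(m$tap_frame),
              model = m$model)
  })
}
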