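#!/usr/bin/env Rscript
# The five target-motion designs: jittering random walk, drifting walk with
# graded step-size variability, fixed fast/slow initial speed, and the eight
# constant-acceleration trajectory kinds with their blocked session design.
# Writes example trajectories and the reconstructed kinematic table.

suppressPackageStartupMessages(library(tapsim))
dir.create("results", showWarnings = FALSE)

# --- jittering target (random walk, +/- 5/3 mm per frame = 20 cm/s) --------
rw <- make_random_walk(60, seed = 1)
cat(sprintf("random walk: %d frames, final position %.1f mm\n",
            rw$n_frames, rw$positions[60]))

# --- drifting targets under the four variability levels --------------------
levels <- c("none", "small", "standard", "large")
examples <- do.call(rbind, lapply(levels, function(lv) {
  sch <- variability_scheme(lv)
  tr <- make_drifting_walk(60, sch$step_options, sch$probabilities,
                           start_pos = -200, seed = 2)
  data.frame(design = paste0("drift_", lv), frame = seq_len(60),
             time_s = tr$times, x_mm = tr$positions)
}))

# --- the eight accelerating/decelerating kinds ------------------------------
specs <- exp5_trajectory_specs()
kin <- do.call(rbind, lapply(specs, function(sp) {
  data.frame(id = sp$id, direction = sp$direction,
             accel_mm_s2 = sp$accel_along, start_mm = sp$start_pos,
             v0_mm_s = sp$v0)
}))
rownames(kin) <- NULL
cat("\nreconstructed trajectory kinds (initial speeds solved from the\n")
cat("constraint of being 325 mm from the approached edge at 700 ms):\n")
print(kin, digits = 4)
cat(sprintf("\nfast - slow initial speed: %.1f mm/s (~14 cm/s)\n",
            kin$v0_mm_s[kin$id == "right_accel_fast"] -
              kin$v0_mm_s[kin$id == "right_accel_slow"]))

accel_examples <- do.call(rbind, lapply(specs, function(sp) {
  tr <- make_accel_trajectory(sp, 120)
  data.frame(design = sp$id, frame = seq_len(120),
             time_s = tr$times, x_mm = tr$positions)
}))

write.csv(rbind(examples, accel_examples),
          "results/target_design_examples.csv", row.names = FALSE)
write.csv(kin, "results/accel_trajectory_kinds.csv", row.names = FALSE)

# --- one blocked session ----------------------------------------------------
blocks <- make_session_blocks(1)
cat(sprintf("\nsession: %d trials in %d blocks (%d reference trials)\n",
            nrow(blocks), length(unique(blocks$block)),
            sum(blocks$block_kind == "reference")))
write.csv(blocks, "results/example_session_blocks.csv", row.names = FALSE)
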