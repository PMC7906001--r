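#!/usr/bin/env Rscript
# Classify every participant's gaze and tool streams into stable / rapid /
# gap events with per-signal adaptive thresholds, and store the event tables
# and the thresholds that were selected. Reads the CSVs written by
# 01_simulate_cohort.R, as an external analyst would.
library(eyehand)

for (scen in c("s1", "s2")) {
  dir <- file.path("results", "data", scen)
  out <- file.path("results", "events", scen)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  roster <- read.csv(file.path(dir, "participants.csv"))
  thetas <- NULL
  for (id in roster$participant) {
    gaze <- read_gaze_table(file.path(dir, paste0("gaze_", id, ".csv")))
    hand <- read_hand_table(file.path(dir, paste0("hand_", id, ".csv")),
                            mode = "permissive")
    sess <- align_session(gaze, hand, offset_ms = "auto")
    eye_ev <- classify_events(sess$gaze)
    hand_ev <- classify_events(sess$hand, channel = "tool")
    write_event_table(eye_ev, file.path(out, paste0("events_eye_", id, ".csv")))
    write_event_table(hand_ev, file.path(out, paste0("events_hand_", id, ".csv")))
    thetas <- rbind(thetas, data.frame(
      participant = id,
      theta_eye_left = eye_ev$threshold$left$theta,
      theta_eye_right = eye_ev$threshold$right$theta,
      theta_tool = hand_ev$threshold$theta))
  }
  write.csv(thetas, file.path(out, "thresholds.csv"), row.names = FALSE)
  cat(sprintf(
    "%s: thresholds ranged %.0f-%.0f px/s (eyes) and %.1f-%.1f units/s (tool)\n",
    scen, min(thetas$theta_eye_left), max(thetas$theta_eye_right),
    min(thetas$theta_tool), max(thetas$theta_tool)))
}
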