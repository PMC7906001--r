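#!/usr/bin/env Rscript
# Reduce the classified events to the six per-task metrics (FD, FN, SN; SSD,
# SSN, SSM), then to participant-level means and group descriptives in the
# layout of the study's descriptive tables.
library(eyehand)

for (scen in c("s1", "s2")) {
  dir <- file.path("results", "data", scen)
  evdir <- file.path("results", "events", scen)
  out <- file.path("results", "metrics")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  roster <- read.csv(file.path(dir, "participants.csv"))
  records <- NULL
  for (i in seq_len(nrow(roster))) {
    id <- roster$participant[i]
    gaze <- read_gaze_table(file.path(dir, paste0("gaze_", id, ".csv")))
    hand <- read_hand_table(file.path(dir, paste0("hand_", id, ".csv")),
                            mode = "permissive")
    sess <- align_session(gaze, hand)
    segs <- segment_tasks(sess, markers = read_markers(
      file.path(dir, paste0("markers_", id, ".csv"))))
    eye_ev <- read_event_table(file.path(evdir, paste0("events_eye_", id, ".csv")))
    hand_ev <- read_event_table(file.path(evdir, paste0("events_hand_", id, ".csv")))
    recs <- session_metrics(eye_ev, hand_ev, segs, participant = id,
                            scenario = toupper(scen))
    recs$group <- roster$group[i]
    records <- rbind(records, recs)
  }
  write_metrics_table(records, file.path(out, paste0("metrics_", scen, ".csv")))
  summ <- summarize_metrics(records)
  write.csv(summ, file.path(out, paste0("summary_", scen, ".csv")),
            row.names = FALSE)
  fd <- summ[summ$metric == "FD", ]
  cat(sprintf("%s: mean FD %.0f ms (intermediate) vs %.0f ms (novice) across %d records\n",
              scen, fd$M[fd$group == "intermediate"],
              fd$M[fd$group == "novice"], nrow(records)))
}
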