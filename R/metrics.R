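# The six coordination metrics, per task segment:
#   eye:  FD  mean fixation duration (ms), FN fixation count, SN saccade count
#   hand: SSD mean stand-still duration (ms), SSN stand-still count,
#         SSM sudden-sharp-movement count
# An event straddling a segment boundary is counted once, in the segment
# containing its midpoint, and contributes the part of its duration that
# falls inside that segment. FD/SSD are missing (NA), not zero, when the
# segment holds no stable event.

segment_event_metrics <- function(events, segment) {
  stopifnot(inherits(events, "event_sequence"))
  ev <- events$events
  if (nrow(ev) == 0L) stop("empty event sequence")
  t0 <- segment$t_start
  t1 <- segment$t_end
  if (ev$t_start[1L] > t0 + 1e-9 || ev$t_end[nrow(ev)] < t1 - 1e-9) {
    stop(sprintf(
      "events [%g, %g) do not cover segment [%g, %g)",
      ev$t_start[1L], ev$t_end[nrow(ev)], t0, t1))
  }
  mid <- (ev$t_start + ev$t_end) / 2
  inseg <- mid >= t0 & mid < t1
  clipped <- pmin(ev$t_end, t1) - pmax(ev$t_start, t0)
  stable <- inseg & ev$kind == "stable"
  rapid <- inseg & ev$kind == "rapid"
  list(
    stable_n = sum(stable),
    rapid_n = sum(rapid),
    stable_mean_ms = if (any(stable)) mean(clipped[stable]) else NA_real_
  )
}

#' Eye metrics for one task segment
#'
#' @param events classified eye `event_sequence` covering the segment.
#' @param segment one task segment: list or one-row data.frame with
#'   `t_start`, `t_end` (ms, half-open).
#' @return list with `FD` (mean clipped fixation duration, ms; `NA` when
#'   `FN = 0`), `FN` (fixation count) and `SN` (saccade count).
#' @export
eye_metrics <- function(events, segment) {
  m <- segment_event_metrics(events, segment)
  list(FD = m$stable_mean_ms, FN = m$stable_n, SN = m$rapid_n)
}

#' Hand metrics for one task segment
#'
#' Same contract as [eye_metrics()] with stable events read as stand-stills
#' and rapid events as sudden sharp movements.
#'
#' @inheritParams eye_metrics
#' @param events classified hand `event_sequence` covering the segment.
#' @return list with `SSD` (mean clipped stand-still duration, ms; `NA` when
#'   `SSN = 0`), `SSN` and `SSM` (counts).
#' @export
hand_metrics <- function(events, segment) {
  m <- segment_event_metrics(events, segment)
  list(SSD = m$stable_mean_ms, SSN = m$stable_n, SSM = m$rapid_n)
}

#' Per-task metric records for one session
#'
#' Applies [eye_metrics()] and [hand_metrics()] to every task segment of an
#' aligned, classified session.
#'
#' @param eye_events classified eye `event_sequence`.
#' @param hand_events classified hand `event_sequence`.
#' @param segments data.frame from [segment_tasks()].
#' @param participant,scenario identifiers stamped on every record.
#' @return data.frame with one row per task: `participant, scenario, task,
#'   FD, FN, SN, SSD, SSN, SSM`.
#' @export
session_metrics <- function(eye_events, hand_events, segments,
                            participant = "p1", scenario = "S1") {
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    e <- eye_metrics(eye_events, seg)
    h <- hand_metrics(hand_events, seg)
    data.frame(participant = participant, scenario = scenario,
               task = seg$task_index,
               FD = e$FD, FN = e$FN, SN = e$SN,
               SSD = h$SSD, SSN = h$SSN, SSM = h$SSM)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level descriptive summary of the metrics
#'
#' Aggregation follows the study design: per task, then mean across a
#' participant's tasks (missing FD/SSD excluded), then mean and sample
#' standard deviation (n - 1) across the participants of each group.
#'
#' @param records data.frame of per-task records ([session_metrics()] rows,
#'   possibly many participants) with an added `group` column, or a separate
#'   `groups` lookup.
#' @param groups optional data.frame `participant, group` when `records`
#'   carries no `group` column.
#' @return data.frame with one row per group x metric: `group, metric, M, SD,
#'   n, single` (`single` flags groups of one participant, whose SD is
#'   reported as 0).
#' @export
summarize_metrics <- function(records, groups = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records: every group needs participants")
  if (is.null(records$group)) {
    if (is.null(groups)) stop("records carry no group column and no groups lookup given")
    records$group <- groups$group[match(records$participant, groups$participant)]
  }
  if (anyNA(records$group)) stop("participant without group label")
  metrics <- c("FD", "FN", "SN", "SSD", "SSN", "SSM")
  pp <- participant_means(records)
  out <- list()
  for (g in unique(records$group)) {
    sub <- pp[pp$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("group with 0 participants: ", g)
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = m,
        M = mean(v),
        SD = if (length(v) > 1L) stats::sd(v) else 0,
        n = length(v),
        single = length(v) == 1L)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Participant-level metric means
#'
#' Mean of each metric over a participant's task records; missing values
#' (tasks with no stable event) are excluded from the mean.
#'
#' @param records per-task records with `participant` and optionally `group`.
#' @return data.frame with one row per participant.
#' @export
participant_means <- function(records) {
  records <- as.data.frame(records)
  metrics <- c("FD", "FN", "SN", "SSD", "SSN", "SSM")
  ids <- unique(records$participant)
  rows <- lapply(ids, function(id) {
    sub <- records[records$participant == id, , drop = FALSE]
    row <- data.frame(participant = id)
    if (!is.null(records$group)) row$group <- sub$group[1L]
    for (m in metrics) row[[m]] <- mean(sub[[m]], na.rm = TRUE)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
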