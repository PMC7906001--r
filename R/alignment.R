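# Gaze and hand are acquired by different devices with independent clocks; the
# study design records both simultaneously, so aligning stream starts (or an
# explicit measured offset) suffices over sessions of a couple of minutes.
# Streams are never resampled: the classifier is sampling-rate independent, so
# each signal keeps its native grid and only the common time window is used.

#' Place the gaze and hand streams on one time scale
#'
#' Applies `offset_ms` to the hand clock (hand time + offset is on the gaze
#' scale) and computes the common half-open window covered by both streams.
#' With `offset_ms = "auto"` the offset aligns stream starts:
#' `offset = t_gaze[1] - t_hand[1]`.
#'
#' @param gaze a [gaze_stream()].
#' @param hand a [hand_stream()].
#' @param offset_ms signed shift in ms applied to the hand clock, or `"auto"`.
#' @return An object of class `session`: list with `gaze`, `hand` (timestamps
#'   shifted onto the gaze scale), `offset_ms`, and `overlap = c(t0, t1)`, the
#'   common window `[t0, t1)`.
#' @export
align_session <- function(gaze, hand, offset_ms = "auto") {
  stopifnot(inherits(gaze, "gaze_stream"), inherits(hand, "hand_stream"))
  if (n_samples(gaze) < 1L || n_samples(hand) < 1L) stop("empty stream")
  if (identical(offset_ms, "auto")) {
    offset_ms <- gaze$samples$t[1L] - hand$samples$t[1L]
  }
  stopifnot(is.numeric(offset_ms), length(offset_ms) == 1L, is.finite(offset_ms))
  hand$samples$t <- hand$samples$t + offset_ms
  gr <- time_range(gaze)
  hr <- time_range(hand)
  t0 <- max(gr[1L], hr[1L])
  t1 <- min(gr[2L], hr[2L])
  if (t0 >= t1) {
    stop(sprintf(
      "alignment error: no overlap between gaze [%g, %g] and shifted hand [%g, %g]",
      gr[1L], gr[2L], hr[1L], hr[2L]))
  }
  structure(list(gaze = gaze, hand = hand, offset_ms = offset_ms,
                 overlap = c(t0, t1)),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> overlap [%g, %g) ms, hand offset %g ms\n",
              x$overlap[1L], x$overlap[2L], x$offset_ms))
  invisible(x)
}

#' Cut a session into per-task segments
#'
#' Tasks are the repeated trials of a scenario (ten per scenario in the
#' emulated design, each at most 10 s). Boundaries come either from an
#' explicit marker table or from a fixed consecutive grid. All segments use
#' the half-open convention `[t_start, t_end)`.
#'
#' @param session a [align_session()] result.
#' @param markers optional data.frame with columns `task_index, t_start,
#'   t_end` and optionally `completed`; all times on the session (gaze) scale
#'   and inside the overlap.
#' @param grid_ms segment length for the fixed grid used when `markers` is
#'   `NULL`; consecutive windows from the overlap start, clipped to the
#'   overlap.
#' @param max_tasks maximum number of segments returned (10 in the emulated
#'   design).
#' @param max_task_ms upper bound on a single segment duration.
#' @return data.frame of segments: `task_index, t_start, t_end, completed`.
#' @export
segment_tasks <- function(session, markers = NULL, grid_ms = 10000,
                          max_tasks = 10L, max_task_ms = 10000) {
  stopifnot(inherits(session, "session"))
  ov <- session$overlap
  if (is.null(markers)) {
    starts <- seq(ov[1L], ov[2L], by = grid_ms)
    starts <- starts[starts < ov[2L]]
    if (length(starts) > max_tasks) starts <- starts[seq_len(max_tasks)]
    segs <- data.frame(task_index = seq_along(starts) - 1L,
                       t_start = starts,
                       t_end = pmin(starts + grid_ms, ov[2L]),
                       completed = TRUE)
  } else {
    need <- c("task_index", "t_start", "t_end")
    miss <- setdiff(need, names(markers))
    if (length(miss) > 0L) {
      stop("markers lack column(s): ", paste(miss, collapse = ", "))
    }
    segs <- data.frame(task_index = as.integer(markers$task_index),
                       t_start = as.numeric(markers$t_start),
                       t_end = as.numeric(markers$t_end),
                       completed = if (is.null(markers$completed)) TRUE
                                   else as.logical(markers$completed))
    segs <- segs[order(segs$t_start), , drop = FALSE]
    rownames(segs) <- NULL
    if (any(segs$t_end <= segs$t_start)) stop("marker with non-positive duration")
    out_of <- segs$t_start < ov[1L] | segs$t_end > ov[2L]
    if (any(out_of)) {
      stop(sprintf("marker for task %d lies beyond the overlap [%g, %g)",
                   segs$task_index[which(out_of)[1L]], ov[1L], ov[2L]))
    }
    if (nrow(segs) > 1L &&
        any(segs$t_start[-1L] < segs$t_end[-nrow(segs)])) {
      stop("overlapping task markers")
    }
    if (nrow(segs) > max_tasks) {
      stop("more than ", max_tasks, " task markers")
    }
  }
  if (any(segs$t_end - segs$t_start > max_task_ms + 1e-9)) {
    stop("task segment exceeds ", max_task_ms, " ms")
  }
  segs
}
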