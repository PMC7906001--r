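# Event classification: speed labels -> run-length grouping -> duration
# filtering -> merged intervals. The same code labels any d-dimensional
# kinematic signal; applied to gaze it yields fixations (stable) and saccades
# (rapid), applied to a haptic trajectory it yields stand-stills and sudden
# sharp movements. Gaps (tracker dropouts, blinks, non-finite positions) are
# first-class intervals: they are never merged into stable events, so a
# fixation split by a blink counts as two fixations.
#
# Grouping/filtering rules, applied in this order to the per-interval labels:
#   (g1) maximal runs of equal labels become candidate intervals;
#   (g2) stable runs shorter than min_stable_ms are relabeled rapid
#        (decided simultaneously on the pre-filter durations);
#   (g3) adjacent same-kind intervals merge;
#   (g4) rapid runs shorter than min_rapid_ms whose two neighbours are both
#        stable are relabeled stable (simultaneously, on post-(g3) durations);
#   (g5) adjacent same-kind intervals merge again;
#   (g6) optionally, gap runs no longer than max_gap_merge_ms flanked by
#        stable on both sides are absorbed (off by default: 0 ms).

#' Classification settings
#'
#' @param min_stable_ms minimum duration of a stable (fixation / stand-still)
#'   interval; shorter stable runs are relabeled rapid. Default 50 ms (at
#'   least 3 gaze samples at 60 Hz, 5 hand samples at 100 Hz).
#' @param min_rapid_ms minimum duration of a rapid interval; shorter rapid
#'   runs flanked by stable intervals on both sides are absorbed into the
#'   stable state. Default 10 ms.
#' @param max_gap_merge_ms gap intervals up to this long flanked by stable
#'   intervals are absorbed into them; 0 disables (the default: gaps never
#'   merge).
#' @param binocular_rule `"both"` labels a gaze interval stable only when
#'   both eyes are sub-threshold (each eye against its own threshold);
#'   `"either"` requires only one.
#' @param median_filter apply a 3-sample running median to the speeds before
#'   thresholding (off by default; raw finite differences).
#' @param k,tolerance,max_iter,floor threshold settings, see
#'   [estimate_threshold()].
#' @return A list of class `event_config`.
#' @export
event_config <- function(min_stable_ms = 50, min_rapid_ms = 10,
                         max_gap_merge_ms = 0,
                         binocular_rule = c("both", "either"),
                         median_filter = FALSE,
                         k = 3, tolerance = 1, max_iter = 50, floor = 1e-6) {
  binocular_rule <- match.arg(binocular_rule)
  stopifnot(min_stable_ms >= 0, min_rapid_ms >= 0, max_gap_merge_ms >= 0)
  structure(list(min_stable_ms = min_stable_ms, min_rapid_ms = min_rapid_ms,
                 max_gap_merge_ms = max_gap_merge_ms,
                 binocular_rule = binocular_rule,
                 median_filter = median_filter,
                 k = k, tolerance = tolerance, max_iter = max_iter,
                 floor = floor),
            class = "event_config")
}

new_event_sequence <- function(signal_id, events, threshold) {
  structure(list(signal_id = signal_id, events = events,
                 threshold = threshold),
            class = "event_sequence")
}

#' @export
print.event_sequence <- function(x, ...) {
  tab <- table(factor(x$events$kind, levels = c("stable", "rapid", "gap")))
  cat(sprintf("<event_sequence> '%s': %d stable, %d rapid, %d gap over [%g, %g) ms\n",
              x$signal_id, tab[["stable"]], tab[["rapid"]], tab[["gap"]],
              if (nrow(x$events)) x$events$t_start[1L] else NA,
              if (nrow(x$events)) x$events$t_end[nrow(x$events)] else NA))
  invisible(x)
}

#' Classify a kinematic stream into stable / rapid / gap intervals
#'
#' Runs the full per-signal pipeline: velocity, adaptive threshold(s), label
#' grouping and duration filtering. The output intervals exactly tile the
#' classified window `[t_1, t_n)`.
#'
#' @param stream a [gaze_stream()], [hand_stream()], or anything
#'   [compute_velocity()] accepts via its default method.
#' @param config an [event_config()].
#' @param ... passed to methods (`channel` for hand streams, `t`/`valid` for
#'   the default method).
#' @return An `event_sequence`: `signal_id`, `events` (data.frame with
#'   `kind`, `t_start`, `t_end`, `duration`, centroid columns), and
#'   `threshold` (one [estimate_threshold()] result, or one per eye).
#' @export
classify_events <- function(stream, config = event_config(), ...) {
  UseMethod("classify_events")
}

#' @rdname classify_events
#' @export
classify_events.gaze_stream <- function(stream, config = event_config(), ...) {
  vel <- compute_velocity(stream)
  sp <- vel$per_channel
  if (config$median_filter) sp <- apply(sp, 2L, median3)
  th_left <- estimate_threshold(sp[, "left"], k = config$k,
                                tolerance = config$tolerance,
                                max_iter = config$max_iter,
                                floor = config$floor)
  th_right <- estimate_threshold(sp[, "right"], k = config$k,
                                 tolerance = config$tolerance,
                                 max_iter = config$max_iter,
                                 floor = config$floor)
  stable_left <- sp[, "left"] < th_left$theta
  stable_right <- sp[, "right"] < th_right$theta
  stable <- if (config$binocular_rule == "both") {
    stable_left & stable_right
  } else {
    stable_left | stable_right
  }
  labels <- ifelse(stable, 1L, 2L)
  labels[!vel$valid] <- 3L
  events <- build_events(labels, vel$bounds, vel$positions, config)
  new_event_sequence("eye", events,
                     list(left = th_left, right = th_right))
}

#' @rdname classify_events
#' @param channel hand channel to classify (`"tool"`, the default, or
#'   `"cam"`).
#' @export
classify_events.hand_stream <- function(stream, config = event_config(),
                                        channel = c("tool", "cam"), ...) {
  channel <- match.arg(channel)
  vel <- compute_velocity(stream, channel = channel)
  classify_velocity(vel, config, signal_id = channel)
}

#' @rdname classify_events
#' @param t,valid timestamps / validity for the default (matrix) method.
#' @param signal_id label recorded on the output sequence.
#' @export
classify_events.default <- function(stream, config = event_config(), t,
                                    valid = NULL, signal_id = "signal", ...) {
  vel <- compute_velocity(stream, t = t, valid = valid)
  classify_velocity(vel, config, signal_id = signal_id)
}

classify_velocity <- function(vel, config, signal_id) {
  sp <- vel$speed
  if (config$median_filter) sp <- median3(sp)
  th <- estimate_threshold(sp, k = config$k, tolerance = config$tolerance,
                           max_iter = config$max_iter, floor = config$floor)
  labels <- ifelse(sp < th$theta, 1L, 2L)
  labels[!vel$valid] <- 3L
  events <- build_events(labels, vel$bounds, vel$positions, config)
  new_event_sequence(signal_id, events, th)
}

median3 <- function(x) {
  nas <- !is.finite(x)
  if (all(nas)) return(x)
  y <- x
  y[nas] <- stats::median(x[!nas])
  out <- stats::runmed(y, k = 3L, endrule = "keep")
  out[nas] <- NA_real_
  as.numeric(out)
}

# labels: 1 stable / 2 rapid / 3 gap, one per inter-sample interval
# bounds: the n sample times (length(labels) + 1)
# positions: n x d matrix for centroids
build_events <- function(labels, bounds, positions, config) {
  runs <- group_runs(labels, bounds, config$min_stable_ms, config$min_rapid_ms,
                     config$max_gap_merge_ms)
  runs <- data.frame(label = runs$label, i_start = runs$i_start,
                     i_end = runs$i_end)
  kinds <- c("stable", "rapid", "gap")
  d <- ncol(positions)
  cen <- matrix(NA_real_, nrow = nrow(runs), ncol = d)
  for (i in seq_len(nrow(runs))) {
    if (runs$label[i] != 3L) {
      # member position samples: both endpoints of every member interval
      idx <- runs$i_start[i]:(runs$i_end[i] + 1L)
      cen[i, ] <- colMeans(positions[idx, , drop = FALSE])
    }
  }
  t_start <- bounds[runs$i_start]
  t_end <- bounds[runs$i_end + 1L]
  ev <- data.frame(kind = kinds[runs$label],
                   t_start = t_start, t_end = t_end,
                   duration = t_end - t_start)
  for (j in seq_len(d)) ev[[paste0("centroid_", j)]] <- cen[, j]
  ev
}

# Run grouping and duration filtering on interval labels. Works entirely at
# the run level: rle once, then vectorised relabel/merge passes. Kept free of
# data.frame construction because it is called once per signal but also
# hundreds of thousands of times by the exhaustive rule-equivalence tests.
# Returns list(label, i_start, i_end) in interval indices.
group_runs <- function(labels, bounds, min_stable_ms, min_rapid_ms,
                       max_gap_merge_ms = 0) {
  if (length(bounds) != length(labels) + 1L) {
    stop("bounds must have one more element than labels")
  }
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lab <- r$values
  # (g2) short stable -> rapid, simultaneous on pre-filter durations
  dur <- bounds[ends + 1L] - bounds[starts]
  lab[lab == 1L & dur < min_stable_ms] <- 2L
  m <- merge_runs(lab, starts, ends)
  # (g4) short rapid flanked by stable on both sides -> stable
  if (length(m$label) >= 3L) {
    dur <- bounds[m$i_end + 1L] - bounds[m$i_start]
    n <- length(m$label)
    inner <- seq(2L, n - 1L)
    flip <- inner[m$label[inner] == 2L & dur[inner] < min_rapid_ms &
                    m$label[inner - 1L] == 1L & m$label[inner + 1L] == 1L]
    m$label[flip] <- 1L
    m <- merge_runs(m$label, m$i_start, m$i_end)
  }
  # (g6) absorb short gaps between stable runs (disabled when 0)
  if (max_gap_merge_ms > 0 && length(m$label) >= 3L) {
    dur <- bounds[m$i_end + 1L] - bounds[m$i_start]
    n <- length(m$label)
    inner <- seq(2L, n - 1L)
    flip <- inner[m$label[inner] == 3L & dur[inner] <= max_gap_merge_ms &
                    m$label[inner - 1L] == 1L & m$label[inner + 1L] == 1L]
    m$label[flip] <- 1L
    m <- merge_runs(m$label, m$i_start, m$i_end)
  }
  m
}

merge_runs <- function(label, i_start, i_end) {
  if (length(label) == 0L) {
    return(list(label = integer(), i_start = integer(), i_end = integer()))
  }
  keep <- c(TRUE, label[-1L] != label[-length(label)])
  last <- c(keep[-1L], TRUE)
  list(label = label[keep], i_start = i_start[keep], i_end = i_end[last])
}
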