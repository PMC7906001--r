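# Delimited-text interchange for all pipeline tables. The canonical dialect is
# plain CSV with a header row; column names can be remapped through `schema`
# (named character vector: canonical name -> column name in the file), because
# tracker/haptic logger exports rarely agree on headers. Times are written as
# milliseconds from stream start at full double precision so read/write
# round-trips are exact.

GAZE_COLS <- c("t_ms", "left_x", "left_y", "right_x", "right_y")
GAZE_OPT_COLS <- c("pupil_left", "pupil_right", "valid_left", "valid_right")
HAND_COLS <- c("t_ms", "tool_x", "tool_y", "tool_z", "cam_x", "cam_y", "cam_z")
HAND_OPT_COLS <- c("tool_rx", "tool_ry", "tool_rz", "cam_rx", "cam_ry", "cam_rz",
                   "valid_tool", "valid_cam")

resolve_schema <- function(header, mandatory, optional, schema = NULL) {
  map <- stats::setNames(c(mandatory, optional), c(mandatory, optional))
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop("schema must be a named character vector (canonical -> file column)")
    }
    unknown <- setdiff(names(schema), c(mandatory, optional))
    if (length(unknown) > 0L) {
      stop("schema maps unknown column(s): ", paste(unknown, collapse = ", "))
    }
    map[names(schema)] <- schema
  }
  missing_cols <- mandatory[!(map[mandatory] %in% header)]
  if (length(missing_cols) > 0L) {
    stop("schema error: mandatory column(s) not found in file: ",
         paste(sprintf("%s (expected header '%s')",
                       missing_cols, map[missing_cols]), collapse = ", "))
  }
  map[map %in% header]
}

read_delim_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a gaze CSV into a gaze stream
#'
#' @param path path to a CSV file with a header row.
#' @param schema optional named character vector remapping canonical column
#'   names (`t_ms`, `left_x`, `left_y`, `right_x`, `right_y`, plus optional
#'   pupil/validity columns) to the column names used in the file.
#' @param screen_w,screen_h screen bounds in pixels used for the default
#'   validity rule.
#' @return A [gaze_stream()].
#' @export
read_gaze_table <- function(path, schema = NULL, screen_w = 1920, screen_h = 1080) {
  raw <- read_delim_table(path)
  map <- resolve_schema(names(raw), GAZE_COLS, GAZE_OPT_COLS, schema)
  if (nrow(raw) < 2L) stop("insufficient data: gaze table has ", nrow(raw), " row(s)")
  out <- data.frame(t = as.numeric(raw[[map[["t_ms"]]]]))
  for (canon in setdiff(names(map), "t_ms")) {
    dest <- sub("_ms$", "", canon)
    val <- raw[[map[[canon]]]]
    out[[dest]] <- if (startsWith(canon, "valid_")) as.logical(val) else as.numeric(val)
  }
  tryCatch(check_time_column(out$t),
           error = function(e) stop("format error in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  gaze_stream(out, screen_w = screen_w, screen_h = screen_h)
}

#' Read a hand CSV into a hand stream
#'
#' @inheritParams read_gaze_table
#' @param mode `"strict"` rejects non-finite position components with an
#'   error; `"permissive"` keeps the rows but flags them invalid so the
#'   classifier treats them as gaps.
#' @return A [hand_stream()].
#' @export
read_hand_table <- function(path, schema = NULL, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  raw <- read_delim_table(path)
  map <- resolve_schema(names(raw), HAND_COLS, HAND_OPT_COLS, schema)
  if (nrow(raw) < 2L) stop("insufficient data: hand table has ", nrow(raw), " row(s)")
  out <- data.frame(t = as.numeric(raw[[map[["t_ms"]]]]))
  for (canon in setdiff(names(map), "t_ms")) {
    val <- raw[[map[[canon]]]]
    out[[canon]] <- if (startsWith(canon, "valid_")) as.logical(val) else as.numeric(val)
  }
  if (mode == "strict") {
    pos <- as.matrix(out[, c("tool_x", "tool_y", "tool_z",
                             "cam_x", "cam_y", "cam_z")])
    bad <- which(!stats::complete.cases(pos) | rowSums(!is.finite(pos)) > 0)
    if (length(bad) > 0L) {
      stop("format error in ", path, ": non-finite position component at row ",
           bad[1L], " (use mode = \"permissive\" to flag such rows as gaps)")
    }
  }
  tryCatch(check_time_column(out$t),
           error = function(e) stop("format error in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  hand_stream(out)
}

#' Write a gaze stream to CSV
#'
#' Writes the canonical gaze columns (`t_ms,left_x,...`) at full double
#' precision; [read_gaze_table()] on the result reconstructs the stream
#' exactly.
#'
#' @param stream a [gaze_stream()].
#' @param path output path.
#' @export
write_gaze_table <- function(stream, path) {
  s <- stream$samples
  out <- data.frame(t_ms = s$t,
                    left_x = s$left_x, left_y = s$left_y,
                    right_x = s$right_x, right_y = s$right_y,
                    pupil_left = s$pupil_left, pupil_right = s$pupil_right,
                    valid_left = s$valid_left, valid_right = s$valid_right)
  write_csv_full(out, path)
}

#' Write a hand stream to CSV
#'
#' @inheritParams write_gaze_table
#' @param stream a [hand_stream()].
#' @export
write_hand_table <- function(stream, path) {
  s <- stream$samples
  cols <- intersect(c("t", "tool_x", "tool_y", "tool_z",
                      "cam_x", "cam_y", "cam_z",
                      "tool_rx", "tool_ry", "tool_rz",
                      "cam_rx", "cam_ry", "cam_rz",
                      "valid_tool", "valid_cam"), names(s))
  out <- s[, cols]
  names(out)[names(out) == "t"] <- "t_ms"
  write_csv_full(out, path)
}

# full-precision CSV writer shared by all tables
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) df[[j]] <- sprintf_trim(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sprintf_trim <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out <- sub("^\\s+", "", out)
  out[is.na(x)] <- "NA"
  out
}

#' Write a classified event sequence to CSV
#'
#' One row per interval: `signal_id,kind,t_start_ms,t_end_ms,duration_ms,
#' centroid_1..centroid_d`. Gap intervals carry `NA` centroids.
#'
#' @param events an [event_sequence] as returned by [classify_events()].
#' @param path output path.
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_sequence"))
  ev <- events$events
  cen <- ev[, grep("^centroid_", names(ev)), drop = FALSE]
  out <- data.frame(signal_id = rep(events$signal_id, nrow(ev)),
                    kind = ev$kind,
                    t_start_ms = ev$t_start, t_end_ms = ev$t_end,
                    duration_ms = ev$duration)
  out <- cbind(out, cen)
  if (nrow(out) == 0L) {
    out <- out[0, , drop = FALSE]
  }
  write_csv_full(out, path)
}

#' Read an event CSV back into an event sequence
#'
#' @param path path written by [write_event_table()].
#' @return An `event_sequence` (without a threshold estimate, which is not
#'   serialized to the event table).
#' @export
read_event_table <- function(path) {
  raw <- read_delim_table(path)
  need <- c("signal_id", "kind", "t_start_ms", "t_end_ms", "duration_ms")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  }
  cen <- raw[, grep("^centroid_", names(raw)), drop = FALSE]
  ev <- data.frame(kind = as.character(raw$kind),
                   t_start = as.numeric(raw$t_start_ms),
                   t_end = as.numeric(raw$t_end_ms),
                   duration = as.numeric(raw$duration_ms))
  for (nm in names(cen)) ev[[nm]] <- as.numeric(cen[[nm]])
  new_event_sequence(
    signal_id = if (nrow(raw) > 0L) raw$signal_id[1L] else "unknown",
    events = ev, threshold = NULL
  )
}

#' Write per-task metric records to CSV
#'
#' Columns: `participant,scenario,task,FD_ms,FN,SN,SSD_ms,SSN,SSM`.
#'
#' @param records data.frame of metric records (see [session_metrics()]).
#' @param path output path.
#' @export
write_metrics_table <- function(records, path) {
  need <- c("participant", "scenario", "task", "FD", "FN", "SN", "SSD", "SSN", "SSM")
  records <- as.data.frame(records)
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L && nrow(records) > 0L) {
    stop("metric records lack column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0L) {
    records <- data.frame(participant = character(), scenario = character(),
                          task = integer(), FD = numeric(), FN = integer(),
                          SN = integer(), SSD = numeric(), SSN = integer(),
                          SSM = integer())
  }
  out <- records[, need]
  names(out) <- c("participant", "scenario", "task",
                  "FD_ms", "FN", "SN", "SSD_ms", "SSN", "SSM")
  write_csv_full(out, path)
}

#' Read a metrics CSV written by [write_metrics_table()]
#'
#' @param path input path.
#' @return data.frame with columns `participant, scenario, task, FD, FN, SN,
#'   SSD, SSN, SSM`.
#' @export
read_metrics_table <- function(path) {
  raw <- read_delim_table(path)
  need <- c("participant", "scenario", "task", "FD_ms", "FN", "SN",
            "SSD_ms", "SSN", "SSM")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("metrics table lacks column(s): ", paste(miss, collapse = ", "))
  }
  data.frame(participant = as.character(raw$participant),
             scenario = as.character(raw$scenario),
             task = as.integer(raw$task),
             FD = as.numeric(raw$FD_ms), FN = as.integer(raw$FN),
             SN = as.integer(raw$SN),
             SSD = as.numeric(raw$SSD_ms), SSN = as.integer(raw$SSN),
             SSM = as.integer(raw$SSM))
}

#' Write task-boundary markers to CSV
#'
#' @param markers data.frame with columns `task_index, t_start, t_end,
#'   completed`.
#' @param path output path.
#' @export
write_markers <- function(markers, path) {
  need <- c("task_index", "t_start", "t_end", "completed")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0L) {
    stop("markers lack column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(task_index = markers$task_index,
                    t_start_ms = markers$t_start, t_end_ms = markers$t_end,
                    completed = markers$completed)
  write_csv_full(out, path)
}

#' Read a task-marker CSV
#'
#' @param path input path.
#' @return data.frame with columns `task_index, t_start, t_end, completed`.
#' @export
read_markers <- function(path) {
  raw <- read_delim_table(path)
  need <- c("task_index", "t_start_ms", "t_end_ms", "completed")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("marker table lacks column(s): ", paste(miss, collapse = ", "))
  }
  data.frame(task_index = as.integer(raw$task_index),
             t_start = as.numeric(raw$t_start_ms),
             t_end = as.numeric(raw$t_end_ms),
             completed = as.logical(raw$completed))
}
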