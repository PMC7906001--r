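#' Construct a binocular gaze stream
#'
#' A gaze stream holds timestamped binocular screen coordinates sampled by an
#' eye tracker at a nominal rate (60 Hz for the device emulated here), in a
#' top-left-origin pixel frame: x grows rightwards, y grows downwards.
#' Samples flagged invalid (blinks, track loss) are retained, not dropped, so
#' that downstream gap handling stays explicit.
#'
#' @param samples data.frame with columns `t` (ms from stream start,
#'   strictly increasing), `left_x`, `left_y`, `right_x`, `right_y` (pixels),
#'   and optionally `pupil_left`, `pupil_right`, `valid_left`, `valid_right`.
#'   Missing validity columns default to "valid iff both coordinates of that
#'   eye are finite and inside the screen bounds".
#' @param nominal_rate_hz sampling rate in Hz; if `NULL`, inferred as
#'   `1000 / median(diff(t))`.
#' @param screen_w,screen_h screen size in pixels.
#' @return An object of class `gaze_stream`: a list with elements `samples`,
#'   `nominal_rate_hz`, `screen_w`, `screen_h`.
#' @export
gaze_stream <- function(samples, nominal_rate_hz = NULL,
                        screen_w = 1920, screen_h = 1080) {
  samples <- as.data.frame(samples)
  need <- c("t", "left_x", "left_y", "right_x", "right_y")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L) {
    stop("gaze samples lack mandatory column(s): ", paste(miss, collapse = ", "))
  }
  check_time_column(samples$t)
  for (eye in c("left", "right")) {
    vcol <- paste0("valid_", eye)
    if (is.null(samples[[vcol]])) {
      x <- samples[[paste0(eye, "_x")]]
      y <- samples[[paste0(eye, "_y")]]
      samples[[vcol]] <- is.finite(x) & is.finite(y) &
        x >= 0 & x < screen_w & y >= 0 & y < screen_h
    } else {
      samples[[vcol]] <- as.logical(samples[[vcol]])
    }
  }
  if (is.null(samples$pupil_left)) samples$pupil_left <- NA_real_
  if (is.null(samples$pupil_right)) samples$pupil_right <- NA_real_
  bad <- which(samples$valid_left &
                 !(is.finite(samples$left_x) & is.finite(samples$left_y) &
                     samples$left_x >= 0 & samples$left_x < screen_w &
                     samples$left_y >= 0 & samples$left_y < screen_h))
  if (length(bad) > 0L) {
    stop("gaze sample flagged valid has left-eye coordinates outside [0, ",
         screen_w, ") x [0, ", screen_h, ") at row ", bad[1L])
  }
  bad <- which(samples$valid_right &
                 !(is.finite(samples$right_x) & is.finite(samples$right_y) &
                     samples$right_x >= 0 & samples$right_x < screen_w &
                     samples$right_y >= 0 & samples$right_y < screen_h))
  if (length(bad) > 0L) {
    stop("gaze sample flagged valid has right-eye coordinates outside screen ",
         "bounds at row ", bad[1L])
  }
  if (is.null(nominal_rate_hz)) nominal_rate_hz <- infer_rate_hz(samples$t)
  stopifnot(nominal_rate_hz > 0)
  rownames(samples) <- NULL
  structure(
    list(samples = samples, nominal_rate_hz = nominal_rate_hz,
         screen_w = screen_w, screen_h = screen_h),
    class = "gaze_stream"
  )
}

#' Construct a hand (haptic device) stream
#'
#' Timestamped 3D tool and camera positions from a haptic interface, nominally
#' at 100 Hz. Device length units are arbitrary but must be used consistently;
#' the adaptive classifier is scale-free so no physical calibration is needed.
#'
#' @param samples data.frame with columns `t` (ms, strictly increasing),
#'   `tool_x`, `tool_y`, `tool_z`, `cam_x`, `cam_y`, `cam_z`, optional
#'   rotations `tool_rx` ... `cam_rz`, and optional logical `valid_tool`,
#'   `valid_cam` (default: valid iff all three position components finite).
#' @param nominal_rate_hz sampling rate in Hz; inferred from timestamps when
#'   `NULL`.
#' @return An object of class `hand_stream`.
#' @export
hand_stream <- function(samples, nominal_rate_hz = NULL) {
  samples <- as.data.frame(samples)
  need <- c("t", "tool_x", "tool_y", "tool_z", "cam_x", "cam_y", "cam_z")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L) {
    stop("hand samples lack mandatory column(s): ", paste(miss, collapse = ", "))
  }
  check_time_column(samples$t)
  for (ch in c("tool", "cam")) {
    vcol <- paste0("valid_", ch)
    fin <- is.finite(samples[[paste0(ch, "_x")]]) &
      is.finite(samples[[paste0(ch, "_y")]]) &
      is.finite(samples[[paste0(ch, "_z")]])
    if (is.null(samples[[vcol]])) {
      samples[[vcol]] <- fin
    } else {
      samples[[vcol]] <- as.logical(samples[[vcol]]) & fin
    }
  }
  if (is.null(nominal_rate_hz)) nominal_rate_hz <- infer_rate_hz(samples$t)
  stopifnot(nominal_rate_hz > 0)
  rownames(samples) <- NULL
  structure(
    list(samples = samples, nominal_rate_hz = nominal_rate_hz),
    class = "hand_stream"
  )
}

check_time_column <- function(t) {
  if (length(t) < 1L) stop("stream has no samples")
  if (anyNA(t) || any(!is.finite(t))) stop("non-finite timestamp")
  if (length(t) > 1L) {
    d <- diff(t)
    bad <- which(d <= 0)
    if (length(bad) > 0L) {
      stop("timestamps not strictly increasing at row ", bad[1L] + 1L,
           " (t = ", t[bad[1L] + 1L], " after t = ", t[bad[1L]], ")")
    }
  }
  invisible(TRUE)
}

infer_rate_hz <- function(t) {
  if (length(t) < 2L) stop("cannot infer sampling rate from fewer than 2 samples")
  1000 / stats::median(diff(t))
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf(
    "<gaze_stream> %d samples, %.1f Hz nominal, %.0f x %.0f px, %.0f-%.0f ms\n",
    nrow(x$samples), x$nominal_rate_hz, x$screen_w, x$screen_h,
    x$samples$t[1L], x$samples$t[nrow(x$samples)]))
  invisible(x)
}

#' @export
print.hand_stream <- function(x, ...) {
  cat(sprintf("<hand_stream> %d samples, %.1f Hz nominal, %.0f-%.0f ms\n",
              nrow(x$samples), x$nominal_rate_hz,
              x$samples$t[1L], x$samples$t[nrow(x$samples)]))
  invisible(x)
}

n_samples <- function(stream) nrow(stream$samples)

time_range <- function(stream) {
  t <- stream$samples$t
  c(t[1L], t[length(t)])
}
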