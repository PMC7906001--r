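# Point-to-point speed is the only feature the classifier uses: raw finite
# differences of position over time, expressed in signal units per second.
# Each speed value sits between two position samples and is assigned the
# half-open interval [t_i, t_{i+1}), so the n samples of a stream yield n-1
# speed intervals that exactly tile [t_1, t_n).

#' Compute a finite-difference velocity series
#'
#' `speed[i] = ||x[i+1] - x[i]|| / (t[i+1] - t[i])`, scaled to units per
#' second (timestamps are in ms). For binocular gaze input the per-eye speeds
#' are computed separately and kept in `per_channel`; `speed` then holds the
#' cyclopean (mean-of-eyes) trajectory speed, which is reported but not used
#' for labeling.
#'
#' @param x a [gaze_stream()], [hand_stream()], or a numeric matrix /
#'   data.frame of positions (one row per sample).
#' @param ... passed to methods.
#' @return An object of class `velocity_series`: list with `t` (interval
#'   start times, ms), `bounds` (the n sample times), `speed` (units/s),
#'   `per_channel` (matrix of per-eye speeds or `NULL`), `valid` (logical:
#'   both bounding samples valid), `positions` (matrix used for centroids).
#' @export
compute_velocity <- function(x, ...) UseMethod("compute_velocity")

#' @rdname compute_velocity
#' @param t timestamps in ms (for the default method).
#' @param valid optional logical validity per sample.
#' @export
compute_velocity.default <- function(x, t, valid = NULL, ...) {
  pos <- as.matrix(x)
  storage.mode(pos) <- "double"
  n <- nrow(pos)
  if (n < 2L) stop("need at least 2 samples to compute velocity")
  if (length(t) != n) stop("positions and timestamps differ in length")
  check_time_column(t)
  if (is.null(valid)) valid <- rep(TRUE, n)
  dt <- diff(t)                     # ms
  disp <- sqrt(rowSums((pos[-1L, , drop = FALSE] -
                          pos[-n, , drop = FALSE])^2))
  speed <- 1000 * disp / dt
  vboth <- valid[-n] & valid[-1L]
  speed[!vboth] <- NA_real_
  structure(list(t = t[-n], bounds = t, speed = speed, per_channel = NULL,
                 valid = vboth, positions = pos),
            class = "velocity_series")
}

#' @rdname compute_velocity
#' @export
compute_velocity.gaze_stream <- function(x, ...) {
  s <- x$samples
  left <- compute_velocity.default(s[, c("left_x", "left_y")], s$t,
                                   valid = s$valid_left)
  right <- compute_velocity.default(s[, c("right_x", "right_y")], s$t,
                                    valid = s$valid_right)
  cyc <- cbind((s$left_x + s$right_x) / 2, (s$left_y + s$right_y) / 2)
  colnames(cyc) <- c("x", "y")
  vboth <- left$valid & right$valid
  cyc_speed <- 1000 * sqrt(rowSums((cyc[-1L, , drop = FALSE] -
                                      cyc[-nrow(cyc), , drop = FALSE])^2)) /
    diff(s$t)
  cyc_speed[!vboth] <- NA_real_
  structure(list(t = s$t[-length(s$t)], bounds = s$t, speed = cyc_speed,
                 per_channel = cbind(left = left$speed, right = right$speed),
                 valid = vboth, positions = cyc),
            class = "velocity_series")
}

#' @rdname compute_velocity
#' @param channel which hand channel to differentiate: the tool (dominant
#'   hand, the default analysed in the study design) or the camera.
#' @export
compute_velocity.hand_stream <- function(x, channel = c("tool", "cam"), ...) {
  channel <- match.arg(channel)
  s <- x$samples
  cols <- paste0(channel, "_", c("x", "y", "z"))
  compute_velocity.default(s[, cols], s$t,
                           valid = s[[paste0("valid_", channel)]])
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %d intervals, median speed %.3g units/s\n",
              length(x$speed), stats::median(x$speed, na.rm = TRUE)))
  invisible(x)
}
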