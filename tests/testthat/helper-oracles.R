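# Independent oracles used across the suite. Each re-derives the expected
# behaviour by a mechanism different from the package implementation.

# Brute-force application of the grouping/filtering rules, working on the
# per-sample label vector with explicit rescans (the implementation works on
# run-length encodings with vectorised passes). labels: 1 stable, 2 rapid,
# 3 gap, one per inter-sample interval; bounds: sample times.
oracle_group_labels <- function(labels, bounds, min_stable_ms, min_rapid_ms) {
  scan_runs <- function(lab) {
    n <- length(lab)
    starts <- integer(n); ends <- integer(n); vals <- integer(n)
    k <- 0L
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && lab[j + 1L] == lab[i]) j <- j + 1L
      k <- k + 1L
      starts[k] <- i; ends[k] <- j; vals[k] <- lab[i]
      i <- j + 1L
    }
    list(label = vals[seq_len(k)], i_start = starts[seq_len(k)],
         i_end = ends[seq_len(k)])
  }
  lab <- as.integer(labels)
  # relabel short stable runs rapid, decisions on the pre-filter runs
  r <- scan_runs(lab)
  for (k in seq_along(r$label)) {
    if (r$label[k] == 1L &&
        bounds[r$i_end[k] + 1L] - bounds[r$i_start[k]] < min_stable_ms) {
      lab[r$i_start[k]:r$i_end[k]] <- 2L
    }
  }
  # relabel short rapid runs flanked by stable on both sides
  r <- scan_runs(lab)
  old_lab <- lab
  for (k in seq_along(r$label)) {
    if (r$label[k] == 2L && k > 1L && k < length(r$label) &&
        r$label[k - 1L] == 1L && r$label[k + 1L] == 1L &&
        bounds[r$i_end[k] + 1L] - bounds[r$i_start[k]] < min_rapid_ms) {
      lab[r$i_start[k]:r$i_end[k]] <- 1L
    }
  }
  scan_runs(lab)
}

# All label sequences of a given length as an integer matrix (3^n rows)
enumerate_label_sequences <- function(n, kinds = 3L) {
  as.matrix(expand.grid(rep(list(seq_len(kinds)), n), KEEP.OUT.ATTRS = FALSE))
}

# Fixed point of the iterated truncated mean + k sd rule on an exact
# N(mu, sigma) distribution: theta' = E[X | X < theta] + k * SD[X | X < theta],
# from closed-form truncated-normal moments.
truncnorm_fixed_point <- function(mu, sigma, k = 3, tol = 1e-10,
                                  max_iter = 10000) {
  trunc_moments <- function(theta) {
    a <- (theta - mu) / sigma
    lambda <- stats::dnorm(a) / stats::pnorm(a)
    m <- mu - sigma * lambda
    v <- sigma^2 * (1 - a * lambda - lambda^2)
    c(m, sqrt(max(v, 0)))
  }
  theta <- mu + k * sigma
  for (i in seq_len(max_iter)) {
    tm <- trunc_moments(theta)
    theta_new <- tm[1L] + k * tm[2L]
    if (abs(theta_new - theta) < tol) return(theta_new)
    theta <- theta_new
  }
  theta
}

# Tiny gaze stream builder: one sample per row of `xy`, at `rate_hz`
tiny_gaze <- function(xy, rate_hz = 60, vergence = 0, valid = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  t <- (seq_len(n) - 1L) * 1000 / rate_hz
  gaze_stream(data.frame(
    t = t,
    left_x = xy[, 1L] - vergence / 2, left_y = xy[, 2L],
    right_x = xy[, 1L] + vergence / 2, right_y = xy[, 2L],
    valid_left = if (is.null(valid)) TRUE else valid,
    valid_right = if (is.null(valid)) TRUE else valid),
    nominal_rate_hz = rate_hz)
}

tiny_hand <- function(xyz, rate_hz = 100, valid = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  t <- (seq_len(n) - 1L) * 1000 / rate_hz
  hand_stream(data.frame(
    t = t,
    tool_x = xyz[, 1L], tool_y = xyz[, 2L], tool_z = xyz[, 3L],
    cam_x = 0, cam_y = 0, cam_z = 0,
    valid_tool = if (is.null(valid)) TRUE else valid,
    valid_cam = TRUE),
    nominal_rate_hz = rate_hz)
}

# Hand-made event sequence over one 2D signal
manual_events <- function(kind, t_start, t_end, cx = 0, cy = 0,
                          signal_id = "eye") {
  ev <- data.frame(kind = kind, t_start = t_start, t_end = t_end,
                   duration = t_end - t_start,
                   centroid_1 = cx, centroid_2 = cy)
  eyehand:::new_event_sequence(signal_id, ev, NULL)
}

# Small spec for fast simulation tests: 3 tasks of 4 s
fast_spec <- function(seed = 1L, ...) {
  cohort_spec(tasks_per_scenario = 3, task_ms = 4000,
              fn_range = c(4L, 7L), fd_range = c(250, 400),
              sn_range = c(2L, 3L),
              ssn_range = c(4L, 7L), ssd_range = c(250, 400),
              ssm_range = c(2L, 3L),
              seed = seed, ...)
}
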