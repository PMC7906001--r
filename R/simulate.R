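# Synthetic cohort generator. Emulates the study's acquisition: per
# participant one scenario session of ten 10-s tasks (separated by short
# masked repositioning intervals), recorded as a 60 Hz binocular gaze stream
# in a 1920x1080 top-left pixel frame and a 100 Hz 3D haptic tool trajectory.
#
# Eye-hand coupling is planted at the per-task metric level through a
# Gaussian copula: each task draws a latent 6-vector, one component per
# metric, from a correlated normal whose cross-correlations are the group's
# profile (FD-SSD, FN-SSN, SN-SSM); monotone maps turn the latents into the
# fixation count, mean fixation duration and saccade count of the task (and
# the hand analogues). Layout per task: FN fixations tiling FN x FD ms,
# separated by FN - 1 transitions of which SN contain a saccade (short,
# 40-60 ms, fast) and the rest are signal-loss gaps (blinks / tracker
# dropouts); gap filler absorbs the remaining budget, which is what makes
# count and duration metrics independently plantable inside a fixed window.
#
# Fixation / stand-still jitter is uniform in a disk (ball in 3D) of fixed
# radius: its inter-sample speed is strictly bounded ABOVE by the adaptive
# mean + 3 sd threshold of the noise itself, so a planted stable interval can
# never emit a spurious supra-threshold sample. All planned durations tile
# each task exactly; planted metrics are recorded from the final layout,
# never re-estimated.

#' Planted coupling profile of a skill group
#'
#' Target latent correlations for the three eye-hand metric pairs. The named
#' profiles mirror the qualitative pattern of the study's correlation tables:
#' strong negative duration/count fixation couplings and strong positive
#' saccade coupling for intermediates; weaker positive couplings for
#' scenario-1-like novices; moderate negative fixation couplings with a
#' near-zero saccade coupling for scenario-2-like novices.
#'
#' @param name `"intermediate"`, `"novice_s1"`, or `"novice_s2"`.
#' @return named numeric vector `c(fd_ssd, fn_ssn, sn_ssm)`.
#' @export
skill_profile <- function(name = c("intermediate", "novice_s1", "novice_s2")) {
  name <- match.arg(name)
  switch(name,
         intermediate = c(fd_ssd = -0.8, fn_ssn = -0.8, sn_ssm = 0.8),
         novice_s1 = c(fd_ssd = 0.45, fn_ssn = 0.45, sn_ssm = 0.55),
         novice_s2 = c(fd_ssd = -0.45, fn_ssn = -0.45, sn_ssm = 0.1))
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults follow the emulated study design: 5 intermediate and 10 novice
#' participants, one scenario of 10 tasks x 10 s with 500 ms masked
#' repositioning intervals between tasks, gaze at 60 Hz on a 1920x1080
#' screen, hand at 100 Hz in arbitrary device units (mm-scale workspace).
#'
#' @param n_intermediate,n_novice group sizes.
#' @param tasks_per_scenario,task_ms,inter_task_ms session layout; the
#'   inter-task intervals are rendered as signal-loss gaps (scene reset).
#' @param eye_rate_hz,hand_rate_hz nominal sampling rates.
#' @param coupling list with entries `intermediate` and `novice`, each a
#'   [skill_profile()]-style vector.
#' @param fn_range,fd_range per-task fixation count range and mean fixation
#'   duration range (ms); `sn_range` the saccade count range (capped at
#'   `FN - 1`). `ssn_range`, `ssd_range`, `ssm_range` are the hand
#'   analogues. Counts, durations and the 40-80 ms rapid events must leave
#'   at least `min_gap_ms` per saccade-free transition inside `task_ms`.
#' @param sac_ms_range,transport_ms_range duration range of individual
#'   saccades / hand transports.
#' @param min_gap_ms minimum duration of a signal-loss gap standing in for a
#'   transition without a rapid event.
#' @param gaze_noise_px fixation jitter disk radius (px).
#' @param hand_noise stand-still jitter ball radius (device units).
#' @param vergence_px fixed horizontal disparity between the two eyes.
#' @param transport_profile position profile along rapid events:
#'   `"constant"` speed (default; sharp onsets) or `"cosine"` ramp.
#' @param blink_rate_per_min extra blink-gap injections per minute of gaze
#'   on top of the planted layout; 0 (default) disables. `blink_ms_range`
#'   bounds their duration.
#' @param t_jitter_ms SD of sampling-time jitter; 0 keeps the nominal grid.
#' @param seed RNG seed consumed by [simulate_cohort()].
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_intermediate = 5, n_novice = 10,
                        tasks_per_scenario = 10, task_ms = 10000,
                        inter_task_ms = 500,
                        eye_rate_hz = 60, hand_rate_hz = 100,
                        coupling = list(intermediate = skill_profile("intermediate"),
                                        novice = skill_profile("novice_s1")),
                        fn_range = c(8L, 15L), fd_range = c(350, 550),
                        sn_range = c(3L, 8L),
                        ssn_range = c(8L, 15L), ssd_range = c(350, 550),
                        ssm_range = c(3L, 8L),
                        sac_ms_range = c(40, 60),
                        transport_ms_range = c(40, 80),
                        min_gap_ms = 60,
                        gaze_noise_px = 2, hand_noise = 0.1,
                        vergence_px = 3,
                        transport_profile = c("constant", "cosine"),
                        blink_rate_per_min = 0, blink_ms_range = c(100, 300),
                        t_jitter_ms = 0, seed = 1L) {
  transport_profile <- match.arg(transport_profile)
  stopifnot(n_intermediate >= 0, n_novice >= 0, tasks_per_scenario >= 1,
            task_ms > 0, inter_task_ms > 0, eye_rate_hz > 0, hand_rate_hz > 0,
            min_gap_ms >= 0, gaze_noise_px > 0, hand_noise > 0)
  for (rng in list(fn_range, fd_range, sn_range, ssn_range, ssd_range,
                   ssm_range, sac_ms_range, transport_ms_range)) {
    stopifnot(length(rng) == 2L, rng[1L] <= rng[2L], rng[1L] > 0)
  }
  stopifnot(fn_range[1L] >= 2, ssn_range[1L] >= 2)
  check_budget <- function(cnt, dur, rap_cnt, rap_ms, what) {
    worst <- cnt[2L] * dur[2L] + rap_cnt[2L] * rap_ms[2L] +
      min_gap_ms * (cnt[2L] - 1L - rap_cnt[1L])
    if (worst >= task_ms) {
      stop(sprintf("%s ranges cannot tile task_ms = %g (worst case %g ms)",
                   what, task_ms, worst))
    }
  }
  check_budget(fn_range, fd_range, sn_range, sac_ms_range, "eye")
  check_budget(ssn_range, ssd_range, ssm_range, transport_ms_range, "hand")
  structure(list(
    n_intermediate = n_intermediate, n_novice = n_novice,
    tasks_per_scenario = tasks_per_scenario, task_ms = task_ms,
    inter_task_ms = inter_task_ms,
    eye_rate_hz = eye_rate_hz, hand_rate_hz = hand_rate_hz,
    coupling = coupling,
    fn_range = as.integer(fn_range), fd_range = fd_range,
    sn_range = as.integer(sn_range),
    ssn_range = as.integer(ssn_range), ssd_range = ssd_range,
    ssm_range = as.integer(ssm_range),
    sac_ms_range = sac_ms_range, transport_ms_range = transport_ms_range,
    min_gap_ms = min_gap_ms,
    gaze_noise_px = gaze_noise_px, hand_noise = hand_noise,
    vergence_px = vergence_px, transport_profile = transport_profile,
    blink_rate_per_min = blink_rate_per_min, blink_ms_range = blink_ms_range,
    t_jitter_ms = t_jitter_ms,
    screen_w = 1920, screen_h = 1080,
    eye_margin = c(200, 150), eye_step_range = c(60, 110),
    hand_box = 80, hand_step_range = c(20, 40),
    seed = as.integer(seed)),
    class = "cohort_spec")
}

# correlation matrix of the 6 task latents (FD, FN, SN, SSD, SSN, SSM);
# accepts a ready-made 6x6 matrix (validated) or a 3-pair profile vector
coupling_matrix <- function(profile) {
  if (is.matrix(profile)) {
    stopifnot(nrow(profile) == 6L, ncol(profile) == 6L)
    if (max(abs(profile - t(profile))) > 1e-12 ||
        max(abs(diag(profile) - 1)) > 1e-12) {
      stop("coupling matrix must be symmetric with unit diagonal")
    }
    check_psd(profile)
    return(profile)
  }
  stopifnot(all(c("fd_ssd", "fn_ssn", "sn_ssm") %in% names(profile)),
            all(abs(profile) <= 1))
  sigma <- diag(6)
  sigma[1L, 4L] <- sigma[4L, 1L] <- profile[["fd_ssd"]]
  sigma[2L, 5L] <- sigma[5L, 2L] <- profile[["fn_ssn"]]
  sigma[3L, 6L] <- sigma[6L, 3L] <- profile[["sn_ssm"]]
  check_psd(sigma)
  sigma
}

check_psd <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("coupling matrix is not positive semi-definite (eigenvalue %.4g)",
                 min(ev)))
  }
  invisible(ev)
}

# n draws from N(0, sigma) via symmetric eigen square root (handles the
# semi-definite |rho| = 1 boundary that chol() rejects)
draw_latents <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  sqrt_s <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(sigma)) %*%
    t(e$vectors)
  matrix(stats::rnorm(n * nrow(sigma)), n, nrow(sigma)) %*% sqrt_s
}

map_count <- function(u, range) {
  lo <- range[1L]; hi <- range[2L]
  as.integer(pmin(lo + floor(u * (hi - lo + 1L)), hi))
}

map_duration <- function(u, range) range[1L] + u * (range[2L] - range[1L])

# positive weights summing to `total`, mildly jittered around equality
split_duration <- function(n, total, shape = 30) {
  if (n == 0L) return(numeric())
  if (n == 1L) return(total)
  w <- stats::rgamma(n, shape = shape, rate = 1)
  w / sum(w) * total
}

# random walk of event centroids with rejection at the box walls
walk_points <- function(n, box_lo, box_hi, step_range) {
  d <- length(box_lo)
  pts <- matrix(NA_real_, n, d)
  pts[1L, ] <- box_lo + stats::runif(d) * (box_hi - box_lo)
  for (i in seq_len(n - 1L)) {
    repeat {
      step <- stats::runif(1L, step_range[1L], step_range[2L])
      dir <- stats::rnorm(d)
      cand <- pts[i, ] + step * dir / sqrt(sum(dir^2))
      if (all(cand >= box_lo) && all(cand <= box_hi)) break
    }
    pts[i + 1L, ] <- cand
  }
  pts
}

# one task block for one signal: FN stable events (durations stable_dur),
# rapid events on `rapid_at` transitions (durations rapid_dur), gap filler on
# the rest and behind rapid events. centroids: one row per stable event.
layout_task_signal <- function(t0, task_ms, centroids, stable_dur, rapid_at,
                               rapid_dur, min_gap_ms) {
  n <- length(stable_dur)
  n_trans <- n - 1L
  has_rapid <- logical(n_trans)
  has_rapid[rapid_at] <- TRUE
  base_gap <- ifelse(has_rapid, 0, min_gap_ms)
  rap_ms <- numeric(n_trans)
  rap_ms[rapid_at] <- rapid_dur
  extra <- task_ms - sum(stable_dur) - sum(rap_ms) - sum(base_gap)
  stopifnot(extra >= -1e-9)
  gap_ms <- base_gap + split_duration(n_trans, max(extra, 0))
  rows <- list()
  t <- t0
  for (j in seq_len(n)) {
    rows[[length(rows) + 1L]] <- event_row("stable", t, t + stable_dur[j],
                                           centroids[j, ], centroids[j, ])
    t <- t + stable_dur[j]
    if (j <= n_trans) {
      if (has_rapid[j]) {
        rows[[length(rows) + 1L]] <- event_row("rapid", t, t + rap_ms[j],
                                               centroids[j, ], centroids[j + 1L, ])
        t <- t + rap_ms[j]
      }
      if (gap_ms[j] > 1e-9) {
        from <- if (has_rapid[j]) centroids[j + 1L, ] else centroids[j, ]
        rows[[length(rows) + 1L]] <- event_row("gap", t, t + gap_ms[j],
                                               from, centroids[j + 1L, ])
        t <- t + gap_ms[j]
      }
    }
  }
  rbind_events(rows)
}

# events are accumulated as numeric rows (kind coded 1 stable / 2 rapid /
# 3 gap) and turned into one data.frame at the end; building a data.frame per
# event would dominate the whole generator's run time
EVENT_KINDS <- c("stable", "rapid", "gap")

event_row <- function(kind, t_start, t_end, from, to) {
  c(match(kind, EVENT_KINDS), t_start, t_end, from, to)
}

rbind_events <- function(rows) {
  m <- do.call(rbind, rows)
  d <- (ncol(m) - 3L) / 2L
  out <- data.frame(kind = EVENT_KINDS[m[, 1L]],
                    t_start = m[, 2L], t_end = m[, 3L])
  for (j in seq_len(d)) out[[paste0("from_", j)]] <- m[, 3L + j]
  for (j in seq_len(d)) out[[paste0("to_", j)]] <- m[, 3L + d + j]
  out
}

#' Plan one participant session
#'
#' Draws the per-task metric latents through the group's coupling profile and
#' lays out the full session: per task an alternating fixation / transition
#' sequence tiling exactly `task_ms` for both signals, plus a masked
#' repositioning gap between consecutive tasks. Consumes the caller's RNG
#' stream.
#'
#' @param spec a [cohort_spec()].
#' @param profile a [skill_profile()]-style coupling vector, or a full 6x6
#'   latent correlation matrix over (FD, FN, SN, SSD, SSN, SSM), which must
#'   be symmetric, unit-diagonal and positive semi-definite.
#' @return An object of class `session_plan`: list with `tasks` (per-task
#'   plans), `eye_events` / `hand_events` (ground-truth interval tables with
#'   path endpoints), `markers`, `planted` (per-task metric values implied by
#'   the layout) and `spec`.
#' @export
plan_tasks <- function(spec, profile = skill_profile("novice_s1")) {
  stopifnot(inherits(spec, "cohort_spec"))
  sigma <- coupling_matrix(profile)
  nt <- spec$tasks_per_scenario
  u <- stats::pnorm(draw_latents(nt, sigma))
  fd <- map_duration(u[, 1L], spec$fd_range)
  fn <- map_count(u[, 2L], spec$fn_range)
  sn <- pmin(map_count(u[, 3L], spec$sn_range), fn - 1L)
  ssd <- map_duration(u[, 4L], spec$ssd_range)
  ssn <- map_count(u[, 5L], spec$ssn_range)
  ssm <- pmin(map_count(u[, 6L], spec$ssm_range), ssn - 1L)

  eye_cen <- walk_points(sum(fn), c(spec$eye_margin[1L], spec$eye_margin[2L]),
                         c(spec$screen_w - spec$eye_margin[1L],
                           spec$screen_h - spec$eye_margin[2L]),
                         spec$eye_step_range)
  hand_cen <- walk_points(sum(ssn), rep(-spec$hand_box, 3L),
                          rep(spec$hand_box, 3L), spec$hand_step_range)

  tasks <- vector("list", nt)
  eye_rows <- list(); hand_rows <- list()
  eye_i <- 0L; hand_i <- 0L
  t_cursor <- 0
  markers <- data.frame(task_index = seq_len(nt) - 1L,
                        t_start = NA_real_, t_end = NA_real_,
                        completed = TRUE)
  for (k in seq_len(nt)) {
    if (k > 1L) {
      # masked repositioning between tasks: signal loss for both streams
      eye_rows[[length(eye_rows) + 1L]] <- rbind_events(list(event_row(
        "gap", t_cursor, t_cursor + spec$inter_task_ms,
        eye_cen[eye_i, ], eye_cen[eye_i + 1L, ])))
      hand_rows[[length(hand_rows) + 1L]] <- rbind_events(list(event_row(
        "gap", t_cursor, t_cursor + spec$inter_task_ms,
        hand_cen[hand_i, ], hand_cen[hand_i + 1L, ])))
      t_cursor <- t_cursor + spec$inter_task_ms
    }
    markers$t_start[k] <- t_cursor
    markers$t_end[k] <- t_cursor + spec$task_ms

    fix_dur <- split_duration(fn[k], fn[k] * fd[k])
    sac_at <- sort(sample.int(fn[k] - 1L, sn[k]))
    sac_dur <- stats::runif(sn[k], spec$sac_ms_range[1L], spec$sac_ms_range[2L])
    eye_rows[[length(eye_rows) + 1L]] <- layout_task_signal(
      t_cursor, spec$task_ms, eye_cen[eye_i + seq_len(fn[k]), , drop = FALSE],
      fix_dur, sac_at, sac_dur, spec$min_gap_ms)
    eye_i <- eye_i + fn[k]

    ss_dur <- split_duration(ssn[k], ssn[k] * ssd[k])
    tr_at <- sort(sample.int(ssn[k] - 1L, ssm[k]))
    tr_dur <- stats::runif(ssm[k], spec$transport_ms_range[1L],
                           spec$transport_ms_range[2L])
    hand_rows[[length(hand_rows) + 1L]] <- layout_task_signal(
      t_cursor, spec$task_ms, hand_cen[hand_i + seq_len(ssn[k]), , drop = FALSE],
      ss_dur, tr_at, tr_dur, spec$min_gap_ms)
    hand_i <- hand_i + ssn[k]

    tasks[[k]] <- list(task_index = k - 1L,
                       fix_durations = fix_dur, sac_durations = sac_dur,
                       stand_durations = ss_dur, transport_durations = tr_dur,
                       planted = c(FD = mean(fix_dur), FN = fn[k], SN = sn[k],
                                   SSD = mean(ss_dur), SSN = ssn[k],
                                   SSM = ssm[k]))
    t_cursor <- t_cursor + spec$task_ms
  }
  planted <- do.call(rbind, lapply(tasks, function(tk) {
    data.frame(task = tk$task_index, t(tk$planted))
  }))
  rownames(planted) <- NULL
  structure(list(tasks = tasks,
                 eye_events = do.call(rbind, eye_rows),
                 hand_events = do.call(rbind, hand_rows),
                 markers = markers, planted = planted, spec = spec),
            class = "session_plan")
}

#' Single-task plan with requested metric values
#'
#' Convenience constructor for tests and examples: one task laid out from
#' explicit counts and mean durations (rapid counts default to their maximum,
#' count - 1, which needs no gap filler beyond the leftover budget).
#'
#' @param fn,fd_ms fixation count and mean fixation duration.
#' @param sn saccade count, at most `fn - 1`.
#' @param ssn,ssd_ms,ssm hand analogues.
#' @param task_ms task duration; the layout must fit it.
#' @param spec a [cohort_spec()] providing geometry, rates and noise; its
#'   count/duration ranges are overridden.
#' @return A one-task `session_plan`.
#' @export
make_task_plan <- function(fn, fd_ms, sn = fn - 1L, ssn = fn, ssd_ms = fd_ms,
                           ssm = ssn - 1L, task_ms = NULL,
                           spec = cohort_spec()) {
  if (!is.null(task_ms)) spec$task_ms <- task_ms
  stopifnot(fn >= 2, ssn >= 2, sn >= 0, sn <= fn - 1, ssm >= 0, ssm <= ssn - 1)
  spec$tasks_per_scenario <- 1L
  spec$fn_range <- c(fn, fn)
  spec$fd_range <- c(fd_ms, fd_ms)
  spec$sn_range <- c(max(sn, 1L), max(sn, 1L))
  spec$ssn_range <- c(ssn, ssn)
  spec$ssd_range <- c(ssd_ms, ssd_ms)
  spec$ssm_range <- c(max(ssm, 1L), max(ssm, 1L))
  plan <- plan_tasks(spec, profile = c(fd_ssd = 0, fn_ssn = 0, sn_ssm = 0))
  if (sn == 0L || ssm == 0L) {
    stop("rapid counts of zero are not representable: every layout needs at least one transition kind")
  }
  plan
}

# position profile along a rapid event: straight line at constant speed, or
# a cosine ramp of the same path
rapid_frac <- function(frac, profile) {
  frac <- pmin(pmax(frac, 0), 1)
  if (profile == "cosine") (1 - cos(pi * frac)) / 2 else frac
}

# uniform jitter in a d-disk/ball of radius a: inter-sample speeds are
# bounded by 2a x rate, which stays below the mean + 3 sd of the jitter's
# own speed distribution, so planted stable intervals never cross the
# adaptive threshold
disk_jitter <- function(n, d, radius) {
  dir <- matrix(stats::rnorm(n * d), n, d)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- radius * stats::runif(n)^(1 / d)
  dir * r
}

# shared renderer: ground-truth events -> noiseless positions + validity on a
# sampling grid
render_positions <- function(events, t, profile) {
  d <- sum(startsWith(names(events), "from_"))
  from <- as.matrix(events[, paste0("from_", seq_len(d)), drop = FALSE])
  to <- as.matrix(events[, paste0("to_", seq_len(d)), drop = FALSE])
  pos <- matrix(NA_real_, length(t), d)
  valid <- rep(TRUE, length(t))
  ev_idx <- findInterval(t, events$t_start)
  ev_idx[ev_idx < 1L] <- 1L
  for (i in seq_len(nrow(events))) {
    sel <- which(ev_idx == i)
    if (length(sel) == 0L) next
    kind <- events$kind[i]
    if (kind == "rapid") {
      dur <- events$t_end[i] - events$t_start[i]
      frac <- rapid_frac((t[sel] - events$t_start[i]) / dur, profile)
      pos[sel, ] <- from[rep(i, length(sel)), , drop = FALSE] +
        outer(frac, to[i, ] - from[i, ])
    } else {
      # stable: hold the centroid; gap: freeze at the entry position
      pos[sel, ] <- matrix(from[i, ], length(sel), d, byrow = TRUE)
      if (kind == "gap") valid[sel] <- FALSE
    }
  }
  list(pos = pos, valid = valid)
}

truth_event_sequence <- function(events, signal_id) {
  d <- sum(startsWith(names(events), "from_"))
  ev <- data.frame(kind = events$kind,
                   t_start = events$t_start, t_end = events$t_end,
                   duration = events$t_end - events$t_start)
  for (j in seq_len(d)) {
    cen <- (events[[paste0("from_", j)]] + events[[paste0("to_", j)]]) / 2
    cen[events$kind == "gap"] <- NA_real_
    ev[[paste0("centroid_", j)]] <- cen
  }
  new_event_sequence(signal_id, ev, NULL)
}

# grid covering [0, t_end]: the last sample lands on or just beyond t_end so
# the classified window [t_1, t_n) contains every planned event
sample_grid <- function(t_end, rate_hz, t_jitter_ms) {
  dt <- 1000 / rate_hz
  t <- seq(0, by = dt, length.out = ceiling(t_end / dt - 1e-9) + 1L)
  if (t_jitter_ms > 0) {
    jit <- stats::rnorm(length(t), sd = t_jitter_ms)
    jit[1L] <- 0
    t <- t + pmin(pmax(jit, -dt / 3), dt / 3)  # keep strict monotonicity
  }
  t
}

check_rate <- function(events, rate_hz) {
  nongap <- events$kind != "gap"
  shortest <- min(events$t_end[nongap] - events$t_start[nongap])
  if (1000 / rate_hz > shortest / 2) {
    stop(sprintf(
      "sampling rate %g Hz too low for the shortest planned event (%g ms)",
      rate_hz, shortest))
  }
  invisible(TRUE)
}

#' Render the gaze stream of a planned session
#'
#' Fixations become bounded jitter around their centroid (both eyes offset by
#' a fixed horizontal vergence disparity, each with independent jitter);
#' saccades become constant-speed straight moves between centroids; gap
#' intervals freeze the reported position and clear both validity flags.
#' Consumes the caller's RNG stream.
#'
#' @param plan a [plan_tasks()] / [make_task_plan()] result.
#' @param rate_hz sampling rate; defaults to the plan's spec.
#' @return list with `stream` (a [gaze_stream()]) and `truth` (the
#'   ground-truth `event_sequence`).
#' @export
render_gaze_stream <- function(plan, rate_hz = NULL) {
  stopifnot(inherits(plan, "session_plan"))
  spec <- plan$spec
  if (is.null(rate_hz)) rate_hz <- spec$eye_rate_hz
  events <- plan$eye_events
  check_rate(events, rate_hz)
  t <- sample_grid(events$t_end[nrow(events)], rate_hz, spec$t_jitter_ms)
  base <- render_positions(events, t, profile = "constant")
  jl <- disk_jitter(length(t), 2L, spec$gaze_noise_px)
  jr <- disk_jitter(length(t), 2L, spec$gaze_noise_px)
  half_v <- spec$vergence_px / 2
  samples <- data.frame(t = t,
                        left_x = base$pos[, 1L] - half_v + jl[, 1L],
                        left_y = base$pos[, 2L] + jl[, 2L],
                        right_x = base$pos[, 1L] + half_v + jr[, 1L],
                        right_y = base$pos[, 2L] + jr[, 2L],
                        pupil_left = 4, pupil_right = 4,
                        valid_left = base$valid, valid_right = base$valid)
  samples <- inject_blinks(samples, spec)
  stream <- gaze_stream(samples, nominal_rate_hz = rate_hz,
                        screen_w = spec$screen_w, screen_h = spec$screen_h)
  list(stream = stream, truth = truth_event_sequence(events, "eye"))
}

inject_blinks <- function(samples, spec) {
  if (spec$blink_rate_per_min <= 0) return(samples)
  dur_min <- (samples$t[nrow(samples)] - samples$t[1L]) / 60000
  n_blinks <- stats::rpois(1L, spec$blink_rate_per_min * dur_min)
  for (i in seq_len(n_blinks)) {
    len <- stats::runif(1L, spec$blink_ms_range[1L], spec$blink_ms_range[2L])
    start <- stats::runif(1L, samples$t[1L], samples$t[nrow(samples)] - len)
    sel <- samples$t >= start & samples$t < start + len
    samples$valid_left[sel] <- FALSE
    samples$valid_right[sel] <- FALSE
  }
  samples
}

#' Render the hand stream of a planned session
#'
#' Stand-stills become bounded 3D jitter around their centroid; transports
#' (the sudden sharp movements) become fast straight moves between centroids
#' (constant speed by default, cosine ramp on request); gap intervals freeze
#' the tool position and clear `valid_tool`, emulating logger dropouts. The
#' camera channel is rendered as a slow smooth drift (it is classified only
#' on request). Consumes the caller's RNG stream.
#'
#' @inheritParams render_gaze_stream
#' @return list with `stream` (a [hand_stream()]) and `truth` (ground-truth
#'   `event_sequence` of the tool channel).
#' @export
render_hand_stream <- function(plan, rate_hz = NULL) {
  stopifnot(inherits(plan, "session_plan"))
  spec <- plan$spec
  if (is.null(rate_hz)) rate_hz <- spec$hand_rate_hz
  events <- plan$hand_events
  check_rate(events, rate_hz)
  t <- sample_grid(events$t_end[nrow(events)], rate_hz, spec$t_jitter_ms)
  base <- render_positions(events, t, profile = spec$transport_profile)
  tool <- base$pos + disk_jitter(length(t), 3L, spec$hand_noise)
  # camera: slow sinusoidal drift around a fixed viewpoint
  phase <- stats::runif(3L, 0, 2 * pi)
  amp <- spec$hand_box / 8
  cam <- cbind(amp * sin(2 * pi * t / 60000 + phase[1L]),
               amp * sin(2 * pi * t / 47000 + phase[2L]),
               amp * sin(2 * pi * t / 71000 + phase[3L])) +
    disk_jitter(length(t), 3L, spec$hand_noise / 2)
  samples <- data.frame(t = t,
                        tool_x = tool[, 1L], tool_y = tool[, 2L],
                        tool_z = tool[, 3L],
                        cam_x = cam[, 1L], cam_y = cam[, 2L], cam_z = cam[, 3L],
                        tool_rx = 0, tool_ry = 0, tool_rz = 0,
                        cam_rx = 0, cam_ry = 0, cam_rz = 0,
                        valid_tool = base$valid, valid_cam = TRUE)
  stream <- hand_stream(samples, nominal_rate_hz = rate_hz)
  list(stream = stream, truth = truth_event_sequence(events, "tool"))
}

#' Simulate one participant
#'
#' @param spec a [cohort_spec()].
#' @param profile coupling profile for the participant's group.
#' @param participant,group identifiers.
#' @return list with `participant`, `group`, `gaze`, `hand`, `markers`,
#'   `truth` (list `eye`, `hand`), `planted` (per-task metric data.frame) and
#'   `plan`.
#' @export
simulate_participant <- function(spec, profile, participant = "p1",
                                 group = "novice") {
  plan <- plan_tasks(spec, profile)
  g <- render_gaze_stream(plan)
  h <- render_hand_stream(plan)
  planted <- cbind(participant = participant, group = group,
                   plan$planted, stringsAsFactors = FALSE)
  list(participant = participant, group = group,
       gaze = g$stream, hand = h$stream, markers = plan$markers,
       truth = list(eye = g$truth, hand = h$truth),
       planted = planted, plan = plan)
}

#' Simulate a full two-group cohort
#'
#' Seeds the RNG from `spec$seed`, then draws intermediates (using
#' `spec$coupling$intermediate`) followed by novices
#' (`spec$coupling$novice`). Identical spec and seed give bit-identical
#' output.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cohort`: list with `participants` (list of
#'   [simulate_participant()] results), `planted` (stacked per-task planted
#'   metrics with group labels) and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ids <- c(sprintf("int%02d", seq_len(spec$n_intermediate)),
           sprintf("nov%02d", seq_len(spec$n_novice)))
  groups <- c(rep("intermediate", spec$n_intermediate),
              rep("novice", spec$n_novice))
  participants <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    profile <- spec$coupling[[groups[i]]]
    participants[[i]] <- simulate_participant(spec, profile, ids[i], groups[i])
  }
  planted <- do.call(rbind, lapply(participants, `[[`, "planted"))
  rownames(planted) <- NULL
  structure(list(participants = participants, planted = planted, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants (%d intermediate, %d novice), %d tasks each\n",
              length(x$participants), x$spec$n_intermediate, x$spec$n_novice,
              x$spec$tasks_per_scenario))
  invisible(x)
}

#' Write a simulated cohort to a directory of CSV files
#'
#' Emits, per participant, `gaze_<id>.csv`, `hand_<id>.csv`,
#' `markers_<id>.csv`, `truth_eye_<id>.csv`, `truth_hand_<id>.csv`, plus
#' cohort-level `participants.csv` and `planted_metrics.csv`. The layout is
#' what [run_pipeline()] in analyze mode reads back.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    write_gaze_table(p$gaze, file.path(dir, paste0("gaze_", p$participant, ".csv")))
    write_hand_table(p$hand, file.path(dir, paste0("hand_", p$participant, ".csv")))
    write_markers(p$markers, file.path(dir, paste0("markers_", p$participant, ".csv")))
    write_event_table(p$truth$eye,
                      file.path(dir, paste0("truth_eye_", p$participant, ".csv")))
    write_event_table(p$truth$hand,
                      file.path(dir, paste0("truth_hand_", p$participant, ".csv")))
  }
  roster <- data.frame(
    participant = vapply(cohort$participants, `[[`, "", "participant"),
    group = vapply(cohort$participants, `[[`, "", "group"))
  write_csv_full(roster, file.path(dir, "participants.csv"))
  write_csv_full(cohort$planted, file.path(dir, "planted_metrics.csv"))
  invisible(dir)
}
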