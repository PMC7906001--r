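# One reproducible run: simulate (or load) a cohort, align and segment each
# participant's session, classify both signals, reduce to the six per-task
# metrics, and produce the group summaries and the normality-gated
# correlation battery, mirroring the study's table structure.

#' Configuration of a pipeline run
#'
#' @param mode `"simulate"` generates the cohort from `spec`; `"analyze"`
#'   reads a [write_cohort()]-layout directory from `data_dir`.
#' @param spec a [cohort_spec()] (simulate mode).
#' @param data_dir directory with `participants.csv`, `gaze_<id>.csv`,
#'   `hand_<id>.csv`, `markers_<id>.csv` (analyze mode). Checked up front so
#'   a bad path fails before any computation.
#' @param scenario identifier stamped on the metric records.
#' @param classify an [event_config()].
#' @param unit correlation unit for [run_correlation_battery()].
#' @param alpha normality-gate level.
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes every intermediate table and the rendered report there.
#' @param seed overrides `spec$seed` when given (simulate mode).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "analyze"), spec = NULL,
                       data_dir = NULL, scenario = "S1",
                       classify = event_config(),
                       unit = c("task", "participant"), alpha = 0.05,
                       out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (mode == "simulate") {
    if (is.null(spec)) spec <- cohort_spec()
    if (!is.null(seed)) spec$seed <- as.integer(seed)
  } else {
    if (is.null(data_dir)) stop("analyze mode needs data_dir")
    roster <- file.path(data_dir, "participants.csv")
    if (!file.exists(roster)) {
      stop("analyze mode: missing roster file ", roster)
    }
    ids <- utils::read.csv(roster, stringsAsFactors = FALSE)$participant
    for (id in ids) {
      for (stem in c("gaze_", "hand_", "markers_")) {
        f <- file.path(data_dir, paste0(stem, id, ".csv"))
        if (!file.exists(f)) stop("analyze mode: missing input file ", f)
      }
    }
  }
  structure(list(mode = mode, spec = spec, data_dir = data_dir,
                 scenario = scenario, classify = classify, unit = unit,
                 alpha = alpha, out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  strip <- config[setdiff(names(config), "out_dir")]
  json <- jsonlite::toJSON(strip, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full coordination pipeline
#'
#' @param config a [run_config()].
#' @return An object of class `run_report`: list with `scenario`,
#'   `summaries` (group descriptives, [summarize_metrics()] shape),
#'   `correlations` ([run_correlation_battery()] table), `records` (per-task
#'   metrics), `thresholds` (per participant and signal), and `provenance`
#'   (seed, config hash, package and R versions).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$spec)
    inputs <- lapply(cohort$participants, function(p) {
      list(participant = p$participant, group = p$group,
           gaze = p$gaze, hand = p$hand, markers = p$markers)
    })
    if (!is.null(config$out_dir)) {
      write_cohort(cohort, file.path(config$out_dir, "data"))
    }
  } else {
    roster <- utils::read.csv(file.path(config$data_dir, "participants.csv"),
                              stringsAsFactors = FALSE)
    inputs <- lapply(seq_len(nrow(roster)), function(i) {
      id <- roster$participant[i]
      list(participant = id, group = roster$group[i],
           gaze = read_gaze_table(file.path(config$data_dir,
                                            paste0("gaze_", id, ".csv"))),
           hand = read_hand_table(file.path(config$data_dir,
                                            paste0("hand_", id, ".csv"))),
           markers = read_markers(file.path(config$data_dir,
                                            paste0("markers_", id, ".csv"))))
    })
  }
  if (length(inputs) == 0L) stop("no participants to analyze")

  all_records <- list()
  thresholds <- list()
  events_out <- list()
  for (p in inputs) {
    session <- align_session(p$gaze, p$hand, offset_ms = "auto")
    segments <- segment_tasks(session, markers = p$markers)
    eye_ev <- classify_events(session$gaze, config$classify)
    hand_ev <- classify_events(session$hand, config$classify, channel = "tool")
    recs <- session_metrics(eye_ev, hand_ev, segments,
                            participant = p$participant,
                            scenario = config$scenario)
    recs$group <- p$group
    all_records[[length(all_records) + 1L]] <- recs
    thresholds[[p$participant]] <- list(
      eye = eye_ev$threshold, hand = hand_ev$threshold)
    events_out[[p$participant]] <- list(eye = eye_ev, hand = hand_ev)
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  summaries <- summarize_metrics(records)
  correlations <- run_correlation_battery(records, unit = config$unit,
                                          alpha = config$alpha)
  report <- structure(list(
    scenario = config$scenario,
    summaries = summaries,
    correlations = correlations,
    records = records,
    thresholds = thresholds,
    provenance = list(
      seed = if (config$mode == "simulate") config$spec$seed else NA_integer_,
      mode = config$mode,
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("eyehand")),
      r_version = paste(R.version$major, R.version$minor, sep = "."))),
    class = "run_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_table(records, file.path(config$out_dir, "metrics.csv"))
    for (id in names(events_out)) {
      write_event_table(events_out[[id]]$eye,
                        file.path(config$out_dir, paste0("events_eye_", id, ".csv")))
      write_event_table(events_out[[id]]$hand,
                        file.path(config$out_dir, paste0("events_hand_", id, ".csv")))
    }
    render_report(report, config$out_dir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> scenario %s: %d records, %d participants\n",
              x$scenario, nrow(x$records),
              length(unique(x$records$participant))))
  print(x$correlations[, c("group", "pair", "method", "coefficient",
                           "strength", "sign", "p")])
  invisible(x)
}

#' Render a run report to disk
#'
#' Writes `report.json` (machine-readable, round-trips through
#' [jsonlite::fromJSON()]) and `report.md` (descriptive and correlation
#' tables in the study's layout).
#'
#' @param report a [run_pipeline()] result.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  if (is.null(report$records) || nrow(report$records) == 0L) {
    stop("nothing to render: report holds no metric records")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  json <- list(scenario = report$scenario,
               summaries = report$summaries,
               correlations = report$correlations,
               provenance = report$provenance)
  jsonlite::write_json(json, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  lines <- c(sprintf("# Coordination report - scenario %s", report$scenario), "")
  lines <- c(lines, "## Descriptive results (participant-level M / SD)", "",
             "| Group | Metric | M | SD | n |", "|---|---|---|---|---|")
  s <- report$summaries
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("| %s | %s | %.2f | %.2f | %d |",
                              s$group[i], s$metric[i], s$M[i], s$SD[i], s$n[i]))
  }
  lines <- c(lines, "", "## Eye-hand correlations", "",
             "| Group | Pair | Method | Coefficient | Strength | p | n |",
             "|---|---|---|---|---|---|---|")
  co <- report$correlations
  for (i in seq_len(nrow(co))) {
    lines <- c(lines, sprintf("| %s | %s | %s | %.3f | %s%s | %.4f | %d |",
                              co$group[i], co$pair[i], co$method[i],
                              co$coefficient[i], co$strength[i], co$sign[i],
                              co$p[i], co$n[i]))
  }
  lines <- c(lines, "",
             sprintf("Provenance: seed %s, config %s, eyehand %s, R %s",
                     report$provenance$seed, report$provenance$config_hash,
                     report$provenance$package_version,
                     report$provenance$r_version))
  writeLines(lines, file.path(path, "report.md"))
  invisible(path)
}
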