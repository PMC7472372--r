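# Monitoring pipeline: decode -> normalize -> estimate -> report.

#' Session configuration for the monitoring pipeline
#'
#' @param phase `"distraction"`, `"consolidation"` or `"calibration"`.
#' @param output_dir Directory for reports (created if missing).
#' @param telemetry_file Optional binary telemetry stream to decode and
#'   normalize.
#' @param events Optional list of [distraction_event()] objects
#'   (distraction phase).
#' @param steps Optional list of per-day lists of [step_record()] objects
#'   (consolidation phase); names are day labels.
#' @param bench Optional bench-grid CSV path or list of
#'   [spring_bench_record()] (calibration phase).
#' @param scenario Optional [synthetic_scenario()] used to simulate missing
#'   inputs.
#' @param sample_rate Hz, in \[5, 50\].
#' @param baseline_window_s Rest window used for baseline normalization, s.
#' @param config An [acquisition_config()].
#' @return Object of class `session_config`.
#' @export
session_config <- function(phase, output_dir,
                           telemetry_file = NULL, events = NULL,
                           steps = NULL, bench = NULL, scenario = NULL,
                           sample_rate = 50, baseline_window_s = 10,
                           config = acquisition_config(sample_rate = sample_rate)) {
  phase <- match.arg(phase, c("distraction", "consolidation", "calibration"))
  if (sample_rate < 5 || sample_rate > 50) {
    stop_fixmon("config", "sample_rate must be in [5, 50] Hz")
  }
  structure(list(phase = phase, output_dir = output_dir,
                 telemetry_file = telemetry_file, events = events,
                 steps = steps, bench = bench, scenario = scenario,
                 sample_rate = sample_rate,
                 baseline_window_s = baseline_window_s,
                 config = config),
            class = "session_config")
}

#' Table-shaped calibration report
#'
#' One calibration row per spring ([summarize_bench()]) plus a phase-average
#' footer row per phase, in the layout of the published bench table.
#'
#' @param bench A bench-grid CSV path (see [read_bench_csv()]) or a list of
#'   [spring_bench_record()] objects.
#' @param path Optional output CSV path.
#' @param k Coverage factor.
#' @return The report `data.frame` (columns `spring_id, phase, Ksr, Ks,
#'   sigma_s, e, U`), invisibly if `path` is given.
#' @export
calibrate_report <- function(bench, path = NULL, k = 2) {
  records <- if (is.character(bench)) read_bench_csv(bench)
             else if (inherits(bench, "spring_bench_record")) list(bench)
             else bench
  if (!length(records)) stop_fixmon("insufficient_data", "no bench records")
  rows <- do.call(rbind, lapply(records, function(r) {
    summarize_bench(r, k = k)[, c("spring_id", "phase", "Ksr", "Ks",
                                  "sigma_s", "e", "U")]
  }))
  rows <- rows[order(rows$phase, rows$Ksr), ]
  footers <- do.call(rbind, lapply(split(rows, rows$phase), function(g) {
    avg <- phase_average(g)
    data.frame(spring_id = "average", phase = g$phase[1], Ksr = NA,
               Ks = NA, sigma_s = NA, e = avg$mean_e, U = avg$mean_U)
  }))
  report <- rbind(rows, footers)
  rownames(report) <- NULL
  if (!is.null(path)) {
    write.csv(report, path, row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Run the monitoring pipeline for one session
#'
#' Depending on the phase: decodes and baseline-normalizes telemetry (if
#' given), estimates stiffness per distraction event or per consolidation
#' day, or builds the calibration report. Writes `stiffness.csv` (columns
#' `phase, day, Kc_N_per_mm, U_percent, n`) or `calibration_report.csv`,
#' plus `session_log.txt` recording frame bookkeeping
#' (`frames_in = frames_decoded + frames_lost`), resynchronization offsets
#' and degenerate steps. Missing inputs are simulated when a scenario is
#' supplied: all distraction days of the protocol, or steps at a planted
#' consolidation stiffness schedule.
#'
#' @param session A [session_config()].
#' @return Invisibly, a list with the report `data.frame`, the log lines and
#'   the paths written.
#' @export
run_pipeline <- function(session) {
  if (!inherits(session, "session_config")) {
    stop_fixmon("config", "session must be a session_config")
  }
  dir.create(session$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  paths <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(session$telemetry_file)) {
    bytes <- readBin(session$telemetry_file, "raw",
                     n = file.size(session$telemetry_file))
    dec <- decode_stream(bytes, session$config)
    n_in <- length(bytes) %/% 15
    note("telemetry: %d bytes in, %d frames decoded, %d frames lost, %d resync events",
         length(bytes), dec$n_frames, n_in - dec$n_frames,
         length(dec$resync_offsets))
    if (length(dec$resync_offsets)) {
      note("resync offsets: %s",
           paste(dec$resync_offsets, collapse = ", "))
    }
    if (dec$n_frames > 0) {
      forces <- counts_to_force(dec$frames, session$config)
      rest <- forces[forces$time_s < session$baseline_window_s, ,
                     drop = FALSE]
      if (nrow(rest) > 0) {
        bl <- compute_baseline(rest)
        forces <- apply_baseline(forces, bl)
        note("baseline from %d samples: %s N", bl$n_samples_used,
             paste(sprintf("%.3f", bl$per_cell_mean), collapse = ", "))
      }
      trace_path <- file.path(session$output_dir, "trace.csv")
      write_trace_csv(forces, trace_path)
      paths <- c(paths, trace_path)
    }
  }

  report <- NULL
  if (session$phase == "calibration") {
    path <- file.path(session$output_dir, "calibration_report.csv")
    report <- calibrate_report(session$bench, path = path)
    paths <- c(paths, path)
    note("calibration report: %d rows", nrow(report))
  } else if (session$phase == "distraction") {
    events <- session$events
    if (is.null(events) && !is.null(session$scenario)) {
      days <- seq_len(session$scenario$protocol$distraction_days)
      events <- lapply(days, function(d)
        simulate_distraction_event(session$scenario, d))
      note("simulated %d distraction events", length(events))
    }
    if (is.null(events)) stop_fixmon("config", "no distraction inputs")
    ests <- lapply(events, distraction_stiffness)
    report <- estimates_frame(ests)
  } else {
    steps <- session$steps
    if (is.null(steps) && !is.null(session$scenario)) {
      sc <- session$scenario
      days <- c(3, 8, 10, 12)
      kc_true <- 530 + (1850 - 530) * (days - min(days)) /
        (max(days) - min(days))
      steps <- lapply(seq_along(days), function(i) {
        lapply(1:5, function(s)
          simulate_step(sc, kc_true[i], step_index = 10L * i + s))
      })
      names(steps) <- days
      note("simulated %d consolidation days x 5 steps", length(days))
    }
    if (is.null(steps)) stop_fixmon("config", "no consolidation inputs")
    ests <- list()
    for (d in names(steps)) {
      est <- tryCatch(
        consolidation_stiffness(steps[[d]], day = as.integer(d)),
        fixmon_degenerate_step_error = function(e) {
          note("day %s: all steps degenerate (%s)", d, conditionMessage(e))
          NULL
        })
      if (!is.null(est)) {
        if (length(attr(est, "degenerate"))) {
          note("day %s: %d degenerate step(s) flagged", d,
               length(attr(est, "degenerate")))
        }
        ests[[d]] <- est
      }
    }
    if (!length(ests)) {
      warning("all steps degenerate; empty stiffness report")
      report <- estimates_frame(list())
    } else {
      report <- estimates_frame(ests)
    }
  }

  if (session$phase != "calibration") {
    path <- file.path(session$output_dir, "stiffness.csv")
    write.csv(report, path, row.names = FALSE)
    paths <- c(paths, path)
    note("stiffness report: %d rows", nrow(report))
  }
  log_path <- file.path(session$output_dir, "session_log.txt")
  writeLines(log_lines, log_path)
  paths <- c(paths, log_path)
  invisible(list(report = report, log = log_lines, paths = paths))
}

estimates_frame <- function(ests) {
  if (!length(ests)) {
    return(data.frame(phase = character(0), day = integer(0),
                      Kc_N_per_mm = numeric(0), U_percent = numeric(0),
                      n = integer(0)))
  }
  do.call(rbind, lapply(ests, function(e) {
    data.frame(phase = e$phase, day = e$day, Kc_N_per_mm = e$Kc,
               U_percent = e$relative_uncertainty, n = e$n)
  }))
}
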