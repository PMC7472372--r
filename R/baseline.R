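# Static-rest baseline normalization.
#
# Load cells drift with temperature, assembly preload and the resting posture
# of the limb. Before a session, measurements are taken with the limb static;
# the per-cell arithmetic mean of that window is the normalization value
# subtracted from all subsequent measurements of the same cell.

#' Compute per-cell baseline offsets from a rest window
#'
#' @param rest_forces A force trace (`data.frame` from [counts_to_force()])
#'   acquired with the limb in a static position. The default window length
#'   used by the pipeline is 10 s at the configured rate.
#' @return A list of class `baseline_offsets` with `per_cell_mean` (newtons,
#'   length 4) and `n_samples_used`.
#' @export
compute_baseline <- function(rest_forces) {
  if (is.null(rest_forces) || nrow(rest_forces) < 1) {
    stop_fixmon("insufficient_data",
                "baseline requires at least one rest sample")
  }
  cols <- c("cell1_N", "cell2_N", "cell3_N", "cell4_N")
  structure(
    list(per_cell_mean = vapply(rest_forces[cols], mean, numeric(1)),
         n_samples_used = nrow(rest_forces)),
    class = "baseline_offsets"
  )
}

#' Subtract baseline offsets from a force trace
#'
#' A pure per-cell shift: each cell's trace minus its rest-window mean, with
#' the four-cell sum recomputed. Variance of every cell is unchanged, and
#' re-running [compute_baseline()] on a normalized rest window yields zeros.
#'
#' @param forces Force trace `data.frame` (see [counts_to_force()]).
#' @param offsets A `baseline_offsets` object from [compute_baseline()].
#' @return The normalized force trace.
#' @export
apply_baseline <- function(forces, offsets) {
  if (!inherits(offsets, "baseline_offsets")) {
    stop_fixmon("config", "offsets must come from compute_baseline()")
  }
  cols <- c("cell1_N", "cell2_N", "cell3_N", "cell4_N")
  for (i in seq_along(cols)) {
    forces[[cols[i]]] <- forces[[cols[i]]] - offsets$per_cell_mean[i]
  }
  forces$sum_N <- forces$cell1_N + forces$cell2_N +
    forces$cell3_N + forces$cell4_N
  forces
}

#' Write a decoded force trace as CSV
#'
#' Columns `time_s, cell1_N..cell4_N, sum_N`, the interchange format consumed
#' by the estimation pipeline.
#'
#' @param forces Force trace `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(forces, path) {
  write.csv(forces, path, row.names = FALSE)
  invisible(path)
}

#' Read a force-trace CSV
#' @param path CSV written by [write_trace_csv()].
#' @return Force trace `data.frame`.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "cell1_N", "cell2_N", "cell3_N", "cell4_N", "sum_N")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_fixmon("parse", paste("trace CSV missing columns:",
                               paste(miss, collapse = ", ")))
  }
  df
}

#' Write the stream-metadata sidecar
#'
#' JSON sidecar holding everything that is deliberately not carried per
#' frame: acquisition configuration, baseline offsets and the wall-clock
#' anchor of the session-relative timestamps.
#'
#' @param path Output JSON path.
#' @param config An [acquisition_config()].
#' @param baseline Optional `baseline_offsets`.
#' @param session_start Wall-clock session start, any scalar representation
#'   (e.g. an ISO 8601 string).
#' @return `path`, invisibly.
#' @export
write_stream_meta <- function(path, config, baseline = NULL,
                              session_start = NULL) {
  meta <- list(
    sample_rate_hz = config$sample_rate,
    adc_bits = config$adc_bits,
    reference_voltage_v = config$reference_voltage,
    per_cell_scale_N_per_count = config$per_cell_scale,
    per_cell_offset_N = config$per_cell_offset,
    sync_mark = paste(sprintf("0x%02X", as.integer(config$sync_mark)),
                      collapse = " "),
    session_start = session_start
  )
  if (!is.null(baseline)) {
    meta$baseline_per_cell_N <- unname(baseline$per_cell_mean)
    meta$baseline_n_samples <- baseline$n_samples_used
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
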